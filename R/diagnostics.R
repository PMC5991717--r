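#' Potential scale reduction factor (Gelman-Rubin diagnostic)
#'
#' Compares between-chain and within-chain variance of a scalar
#' parameter:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}},}
#' where `W` is the mean within-chain variance and `B/n` the variance of
#' the chain means. Values near 1 indicate the chains are sampling the
#' same distribution; fits flag parameters with \eqn{\hat R > 1.05}.
#'
#' @param chains a numeric matrix with one column per chain (equal
#'   lengths), or a list of equal-length numeric vectors.
#' @return the PSRF, a single number.
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    len <- lengths(chains)
    stopifnot(length(unique(len)) == 1)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) {
    abort("PSRF requires at least 2 chains.",
          class = "bacinet_validation_error")
  }
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(colMeans(chains))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size of pooled MCMC draws
#'
#' Autocorrelation-corrected sample size, summed over chains. The
#' integrated autocorrelation time is estimated per chain from the
#' empirical autocorrelation function, truncated at the first
#' non-positive value (initial positive sequence rule).
#'
#' @param chains numeric matrix, one column per chain.
#' @return estimated effective sample size.
#' @export
ess <- function(chains) {
  chains <- as.matrix(chains)
  per_chain <- apply(chains, 2, function(x) {
    n <- length(x)
    if (var(x) == 0) return(n)
    rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    neg <- which(rho <= 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    n / (1 + 2 * sum(rho))
  })
  sum(per_chain)
}
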