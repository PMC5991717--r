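#' Equal-tailed credible interval from posterior draws
#'
#' Percentile interval at probabilities `(1 - level)/2` and
#' `1 - (1 - level)/2`, using linear interpolation between order
#' statistics (R's default quantile type 7). With the draw counts used
#' here, competing percentile conventions agree to reporting precision.
#'
#' @param draws numeric vector of posterior draws.
#' @param level credible level in (0, 1).
#' @return numeric length-2 vector `c(low, high)`.
#' @examples
#' credible_interval(1:100)          # approx (3.5, 97.5)
#' credible_interval(rep(2, 500))    # zero width at 2
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) == 0) {
    abort("Cannot form a credible interval from zero draws.",
          class = "bacinet_validation_error")
  }
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
}

#' Does a credible interval exclude zero?
#'
#' Closed-interval convention: an endpoint exactly at 0 counts as
#' overlapping zero, so the result is `FALSE`.
#'
#' @param interval numeric length-2 `c(low, high)` with `low <= high`.
#' @return `TRUE` iff the whole interval is strictly above or strictly
#'   below zero.
#' @export
excludes_zero <- function(interval) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2])
  interval[1] > 0 || interval[2] < 0
}

#' Do two closed intervals overlap?
#'
#' Touching endpoints count as overlap. Symmetric and reflexive.
#'
#' @param a,b numeric length-2 intervals `c(low, high)`.
#' @return `TRUE` iff the closed intervals intersect.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  a[1] <= b[2] && b[1] <= a[2]
}

#' Posterior of the before-after difference in mean catch
#'
#' Forms draws of \eqn{D = M_{post} - M_{pre}} by pairing the retained
#' draws of the two independent period fits by index (chains are
#' truncated to the shorter fit; for independent posteriors the pairing
#' order is statistically irrelevant but fixing it makes runs
#' reproducible), and summarizes `D` by its posterior mean, equal-tailed
#' credible interval, and `P(D > 0)`. Units are fish per gill-net set;
#' positive values mean catch increased after the change.
#'
#' @param post,pre `pln_fit` objects for the Post and Pre periods of the
#'   same lake x species.
#' @param level credible level.
#' @return a one-row tibble (`lake`, `species`, `post_mean`, `ci_low`,
#'   `ci_high`, `prob_positive`, `n_draws`, `converged`), with the
#'   difference draws attached as attribute `"draws"`.
#' @export
difference_posterior <- function(post, pre, level = 0.95) {
  stopifnot(inherits(post, "pln_fit"), inherits(pre, "pln_fit"))
  n <- min(nrow(post$draws), nrow(pre$draws))
  if (n == 0) {
    abort("No retained draws to pair.", class = "bacinet_validation_error")
  }
  d <- post$draws$M[seq_len(n)] - pre$draws$M[seq_len(n)]
  ci <- credible_interval(d, level)
  grp <- post$group %||% pre$group %||% list()
  out <- tibble::tibble(
    lake = grp$lake %||% NA_character_,
    species = grp$species %||% NA_character_,
    post_mean = mean(d), ci_low = ci[1], ci_high = ci[2],
    prob_positive = mean(d > 0), n_draws = n,
    converged = !any(c(post$diagnostics$psrf, pre$diagnostics$psrf) > 1.05,
                     na.rm = TRUE))
  attr(out, "draws") <- d
  out
}

#' Classify before-after differences against the control lakes
#'
#' Applies the credible-interval-overlap decision rule of a BACI design:
#' for each species, an impact lake's before-after difference is compared
#' with every control lake's difference. A row is flagged
#' `excludes_zero` when its own interval is clear of zero, and an impact
#' row's verdict is `"distinct-from-all-controls"` only when its interval
#' overlaps no control interval -- the design's evidence that the impact
#' changed that species' catch rate. Impact rows whose interval overlaps
#' at least one control are `"consistent-with-some-control"`; species
#' lacking a fitted control (or impact rows where no control row exists)
#' yield `"indeterminate"` with a warning. Control rows carry verdict
#' `"control"`.
#'
#' The full per-species pairwise overlap matrix (all lakes, controls
#' included) is attached as attribute `"overlap_matrices"` so conclusions
#' that depend on the choice of control lake can be inspected directly.
#'
#' @param summaries a tibble of difference summaries, one row per lake x
#'   species, with columns `lake`, `species`, `post_mean`, `ci_low`,
#'   `ci_high` (as produced by [difference_posterior()] /
#'   [baci_differences()]).
#' @param roles named character vector mapping lake to `"control"` or
#'   `"impact"`; defaults to [default_lake_roles()].
#' @return a `baci_report` tibble: the input columns plus `role`,
#'   `excludes_zero`, `overlaps_controls` (named-logical list column,
#'   one entry per control lake), and `verdict`.
#' @export
classify_baci <- function(summaries, roles = default_lake_roles()) {
  stopifnot(nrow(summaries) > 0,
            all(c("lake", "species", "ci_low", "ci_high") %in%
                  names(summaries)))
  unknown <- setdiff(unique(summaries$lake), names(roles))
  if (length(unknown)) {
    abort(paste0("No control/impact role declared for: ",
                 paste(unknown, collapse = ", ")),
          class = "bacinet_validation_error")
  }
  summaries$role <- unname(roles[summaries$lake])

  overlap_mats <- list()
  rows <- summaries |>
    dplyr::group_by(.data$species) |>
    dplyr::group_split()
  out <- purrr::map_dfr(rows, function(sp) {
    controls <- sp[sp$role == "control", ]
    ints <- Map(c, sp$ci_low, sp$ci_high)
    names(ints) <- sp$lake
    mat <- outer(seq_along(ints), seq_along(ints),
                 Vectorize(function(i, j) intervals_overlap(ints[[i]],
                                                            ints[[j]])))
    dimnames(mat) <- list(sp$lake, sp$lake)
    overlap_mats[[sp$species[1]]] <<- mat
    sp$excludes_zero <- purrr::map2_lgl(sp$ci_low, sp$ci_high,
                                        ~excludes_zero(c(.x, .y)))
    sp$overlaps_controls <- purrr::map(seq_len(nrow(sp)), function(i) {
      ov <- purrr::map_lgl(seq_len(nrow(controls)), function(k) {
        intervals_overlap(ints[[sp$lake[i]]],
                          c(controls$ci_low[k], controls$ci_high[k]))
      })
      stats::setNames(ov, controls$lake)
    })
    sp$verdict <- purrr::map_chr(seq_len(nrow(sp)), function(i) {
      if (sp$role[i] == "control") return("control")
      others <- controls[controls$lake != sp$lake[i], ]
      if (nrow(others) == 0) return("indeterminate")
      ov <- sp$overlaps_controls[[i]][others$lake]
      if (any(ov)) "consistent-with-some-control" else
        "distinct-from-all-controls"
    })
    if (any(sp$verdict == "indeterminate")) {
      warn(paste0("Species `", sp$species[1],
                  "` has no fitted control lake; verdict indeterminate."))
    }
    sp
  })
  attr(out, "overlap_matrices") <- overlap_mats
  class(out) <- c("baci_report", class(out))
  out
}

#' Per-species credible-interval overlap matrices of a BACI report
#'
#' @param report a `baci_report` from [classify_baci()].
#' @return a named list (by species) of logical lake-by-lake matrices.
#' @export
overlap_matrices <- function(report) {
  attr(report, "overlap_matrices")
}

#' Render a BACI report as a compact table
#'
#' Species-major order with control lakes first; differences are shown as
#' `mean (low to high)` rounded to two decimals (round-half-even), and
#' rows whose interval excludes zero are marked with `*`.
#'
#' @param report a `baci_report`.
#' @param format `"markdown"` or `"tsv"`.
#' @param metadata optional named list (e.g. version, seed, priors)
#'   embedded as `#`-comment header lines.
#' @return a single string.
#' @export
render_baci_table <- function(report, format = c("markdown", "tsv"),
                              metadata = NULL) {
  format <- match.arg(format)
  stopifnot(nrow(report) > 0)
  ord <- report |>
    dplyr::arrange(.data$species,
                   dplyr::desc(.data$role == "control"), .data$lake)
  cell <- sprintf("%.2f (%.2f to %.2f)%s", ord$post_mean, ord$ci_low,
                  ord$ci_high, ifelse(ord$excludes_zero, " *", ""))
  lake_lab <- ifelse(ord$role == "control", paste0(ord$lake, " (C)"),
                     ord$lake)
  hdr <- if (is.null(metadata)) character(0) else
    paste0("# ", names(metadata), "=",
           vapply(metadata, function(x) paste(format(x), collapse = ","),
                  ""))
  if (format == "tsv") {
    body <- c("lake\tspecies\tdifference\tverdict",
              paste(lake_lab, ord$species, cell, ord$verdict, sep = "\t"))
  } else {
    body <- c("| Lake | Species | Difference (95% CrI) | Verdict |",
              "|---|---|---|---|",
              sprintf("| %s | %s | %s | %s |", lake_lab, ord$species, cell,
                      ord$verdict))
    hdr <- if (length(hdr)) c(hdr, "") else hdr
  }
  paste(c(hdr, body), collapse = "\n")
}
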