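# fixtures shared across test files; everything is generated in code

toy_catch <- function() {
  tibble::tibble(
    lake = c("LakeX", "LakeX", "LakeY"),
    station = c("a", "a", "b"),
    year = c(1995L, 1995L, 2006L),
    species = c("Walleye", "Walleye", "Walleye"),
    count = c(3L, 0L, 7L)
  )
}

# full two-station grid over given years, one set per station-year
grid_catch <- function(lakes = "LakeX", stations = c("A", "B"),
                       years = 1990:2014, species = "Walleye",
                       count = 1L) {
  df <- tidyr::expand_grid(lake = lakes, station = stations, year = years,
                           species = species)
  df$count <- count
  df
}

# random toy table for property-style tests
random_catch <- function(n = 120, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    lake = sample(c("L1", "L2", "L3"), n, replace = TRUE),
    station = sample(c("s1", "s2", "s3", "s4"), n, replace = TRUE),
    year = sample(1988:2016, n, replace = TRUE),
    species = sample(c("Walleye", "Yellow Perch"), n, replace = TRUE),
    count = rpois(n, 4)
  ))
}

# light sampler settings for tests that only need a rough posterior
fast_config <- function(seed = 1, ...) {
  mcmc_config(chains = 2, iterations = 5000, burn_in = 1500, thin = 2,
              seed = seed, ...)
}

# settings for tests that compare posterior moments quantitatively
precise_config <- function(seed = 1) {
  mcmc_config(chains = 4, iterations = 160000, burn_in = 10000, thin = 2,
              seed = seed)
}

# priors with a bounded dispersion tail, used wherever MCMC is compared
# to the quadrature oracle (the group mean has heavy tails under very
# diffuse dispersion priors and tiny n, which only inflates Monte Carlo
# error without changing what is being validated)
oracle_priors <- function() pln_priors(mu_mean = 0, mu_sd = 5,
                                       sigma_upper = 2)

# a one-row difference summary for interval-logic tests
summary_row <- function(lake, species, lo, hi) {
  tibble::tibble(lake = lake, species = species,
                 post_mean = (lo + hi) / 2, ci_low = lo, ci_high = hi)
}
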