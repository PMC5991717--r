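test_that("credible_interval follows the interpolated-percentile convention", {
  # rank-statistic recount for quantile type 7: at p the value is
  # x[(n-1)p + 1] with linear interpolation
  x <- withr::with_seed(9, sample(1:100))
  ci <- credible_interval(x, 0.95)
  h_lo <- (100 - 1) * 0.025 + 1
  h_hi <- (100 - 1) * 0.975 + 1
  xo <- sort(x)
  expect_equal(ci[1], xo[floor(h_lo)] + (h_lo - floor(h_lo)) *
                 (xo[ceiling(h_lo)] - xo[floor(h_lo)]))
  expect_equal(ci[2], xo[floor(h_hi)] + (h_hi - floor(h_hi)) *
                 (xo[ceiling(h_hi)] - xo[floor(h_hi)]))
  expect_equal(round(ci), c(3, 98))

  expect_equal(credible_interval(rep(2.5, 300)), c(2.5, 2.5))

  # symmetric draws: 50% interval symmetric about the median
  z <- withr::with_seed(10, { z0 <- rnorm(5000); c(z0, -z0) })
  ci50 <- credible_interval(z, 0.5)
  expect_equal(ci50[1] + ci50[2], 2 * stats::median(z), tolerance = 1e-8)

  expect_error(credible_interval(numeric(0)),
               class = "bacinet_validation_error")
})

test_that("zero-exclusion and overlap use closed-interval conventions", {
  expect_true(excludes_zero(c(3.12, 5.34)))
  expect_false(excludes_zero(c(-1.32, 0.97)))
  expect_false(excludes_zero(c(0, 1)))      # endpoint at zero: not excluded
  expect_true(excludes_zero(c(-2, -0.5)))

  expect_true(intervals_overlap(c(0.68, 4.01), c(-1.32, 0.97)))
  expect_false(intervals_overlap(c(3.12, 5.34), c(-1.32, 0.97)))
  expect_true(intervals_overlap(c(0, 1), c(1, 2)))  # touching endpoints
})

test_that("interval logic matches an exhaustive pairwise oracle on random pairs", {
  set.seed(77)
  for (k in 1:1000) {
    a <- sort(runif(2, -5, 5)); b <- sort(runif(2, -5, 5))
    # independent formulation: overlap iff neither lies wholly beyond the other
    brute <- !(a[2] < b[1] || b[2] < a[1])
    expect_identical(intervals_overlap(a, b), brute)
    # symmetry and reflexivity
    expect_identical(intervals_overlap(a, b), intervals_overlap(b, a))
    expect_true(intervals_overlap(a, a))
    # zero-exclusion vs direct sign test
    expect_identical(excludes_zero(a), (a[1] > 0) == (a[2] > 0) && a[1] != 0)
  }
})

test_that("difference_posterior pairs draws by index and is antisymmetric", {
  y <- withr::with_seed(41, rpois(60, exp(rnorm(60, 1.2, 0.6))))
  pre <- fit_pln_group(y, config = fast_config(seed = 3),
                       group = list(lake = "L", species = "S",
                                    period = "Pre"))
  post <- fit_pln_group(y, config = fast_config(seed = 3),
                        group = list(lake = "L", species = "S",
                                     period = "Post"))
  # identical fits: self-difference is exactly zero draw-wise
  d_self <- difference_posterior(post, pre)
  expect_true(all(attr(d_self, "draws") == 0))
  expect_false(excludes_zero(c(d_self$ci_low, d_self$ci_high)))
  expect_equal(d_self$lake, "L")

  pre2 <- fit_pln_group(y, config = fast_config(seed = 4))
  d_ab <- difference_posterior(post, pre2)
  d_ba <- difference_posterior(pre2, post)
  expect_equal(attr(d_ab, "draws"), -attr(d_ba, "draws"))
  expect_equal(d_ab$post_mean, -d_ba$post_mean)
  expect_equal(c(d_ab$ci_low, d_ab$ci_high),
               -c(d_ba$ci_high, d_ba$ci_low))

  # unequal retained lengths truncate to the shorter fit
  short <- fit_pln_group(y, config = mcmc_config(chains = 2,
                                                 iterations = 3000,
                                                 burn_in = 1000, thin = 2,
                                                 seed = 5))
  d <- difference_posterior(post, short)
  expect_equal(d$n_draws, nrow(short$draws))
})

test_that("difference recovers a known injected change in mean catch", {
  # true M: pre 4, post 7 (mu chosen by the lognormal mean identity)
  sg <- 0.5
  pre_y <- simulate_group(group_spec("L", "S", "Pre",
                                     mu = log(4) - sg^2 / 2, sigma = sg,
                                     n_stations = 15), seed = 61)
  post_y <- simulate_group(group_spec("L", "S", "Post",
                                      mu = log(7) - sg^2 / 2, sigma = sg,
                                      n_stations = 15), seed = 62)
  pre <- fit_pln_group(pre_y, config = fast_config(seed = 6))
  post <- fit_pln_group(post_y, config = fast_config(seed = 7))
  d <- difference_posterior(post, pre)
  expect_equal(d$post_mean, 3, tolerance = 0.25)
  expect_gt(d$prob_positive, 0.99)
})

test_that("classify_baci applies the control-overlap rule and surfaces the matrix", {
  # three-species report built from published-style intervals
  rows <- dplyr::bind_rows(
    summary_row("CtrlA", "Perch", -1.63, 0.62),
    summary_row("CtrlB", "Perch", -9.5, -2.26),
    summary_row("Imp1", "Perch", 2.93, 5.57),
    summary_row("Imp2", "Perch", -0.77, 0.58))
  roles <- c(CtrlA = "control", CtrlB = "control",
             Imp1 = "impact", Imp2 = "impact")
  rep <- classify_baci(rows, roles)
  v <- setNames(rep$verdict, rep$lake)
  expect_equal(v[["Imp1"]], "distinct-from-all-controls")
  expect_equal(v[["Imp2"]], "consistent-with-some-control")
  expect_equal(v[["CtrlA"]], "control")
  mats <- overlap_matrices(rep)
  expect_true(is.matrix(mats$Perch))
  expect_false(mats$Perch["Imp1", "CtrlA"])

  # an impact interval equal to a control interval is consistent
  rows2 <- dplyr::bind_rows(summary_row("CtrlA", "W", 1, 2),
                            summary_row("Imp1", "W", 1, 2))
  rep2 <- classify_baci(rows2, roles)
  expect_equal(rep2$verdict[rep2$lake == "Imp1"],
               "consistent-with-some-control")

  # missing control: indeterminate with a warning
  rows3 <- summary_row("Imp1", "W", 1, 2)
  expect_warning(rep3 <- classify_baci(rows3, roles), "indeterminate")
  expect_equal(rep3$verdict, "indeterminate")

  # undeclared lake is an error
  expect_error(classify_baci(summary_row("Mystery", "W", 0, 1), roles),
               class = "bacinet_validation_error")
})

test_that("classify_baci agrees with a brute-force overlap scan on random reports", {
  set.seed(123)
  for (k in 1:25) {
    n_ctrl <- sample(1:3, 1); n_imp <- sample(1:4, 1)
    lakes <- c(paste0("C", seq_len(n_ctrl)), paste0("I", seq_len(n_imp)))
    roles <- setNames(c(rep("control", n_ctrl), rep("impact", n_imp)), lakes)
    rows <- purrr::map_dfr(lakes, function(lk) {
      iv <- sort(runif(2, -4, 4))
      summary_row(lk, "sp", iv[1], iv[2])
    })
    rep <- classify_baci(rows, roles)
    for (i in which(rep$role == "impact")) {
      any_overlap <- FALSE
      for (j in which(rep$role == "control")) {
        if (max(rep$ci_low[i], rep$ci_low[j]) <=
            min(rep$ci_high[i], rep$ci_high[j])) any_overlap <- TRUE
      }
      expect_equal(rep$verdict[i],
                   if (any_overlap) "consistent-with-some-control" else
                     "distinct-from-all-controls")
    }
  }
})

test_that("render_baci_table formats to two decimals with significance marks", {
  rows <- dplyr::bind_rows(summary_row("CtrlA", "W", 0.1, 2.3),
                           summary_row("Imp1", "W", -1, 1))
  rows$post_mean[1] <- 1.234
  rep <- classify_baci(rows, c(CtrlA = "control", Imp1 = "impact"))
  txt <- render_baci_table(rep, "tsv", metadata = list(seed = 7))
  expect_match(txt, "1.23 (0.10 to 2.30) *", fixed = TRUE)
  expect_match(txt, "# seed=7", fixed = TRUE)
  # controls sort first within species
  lines <- strsplit(txt, "\n")[[1]]
  expect_lt(grep("CtrlA", lines), grep("Imp1", lines))

  md <- render_baci_table(rep, "markdown")
  expect_match(md, "\\| Lake \\|")
})
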