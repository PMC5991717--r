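Package: bacinet
Title: Bayesian Before-After Control-Impact Analysis of Gill-Net Catch Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for before-after, control-impact (BACI) analysis of
    standardized gill-net survey counts. Mean catch per gill-net set is
    estimated per lake, species and period with a hierarchical
    Poisson-lognormal model fitted by a Metropolis-within-Gibbs sampler;
    before-after differences are summarized as posterior means with
    equal-tailed credible intervals, and impact lakes are compared to
    control lakes with a credible-interval-overlap decision rule.
    Includes data filtering utilities for long-term survey records, a
    brute-force quadrature oracle for validating the sampler on small
    groups, and a synthetic-survey generator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    rjags,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
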