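---
title: "Methods: a Bayesian BACI analysis of gill-net catch counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian BACI analysis of gill-net catch counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long-term standardized gill-net surveys index the relative abundance of
fish (catch per unit effort, CPUE: fish caught per net set). When a
management intervention — here, the change in reservoir water-level rules
implemented in 2000 for the Rainy–Namakan lake complex — might have
altered fish communities, a before-after/control-impact (BACI) design
asks whether the change in CPUE from the before period to the after
period differs between lakes affected by the intervention and unaffected
control lakes. `bacinet` implements that analysis end to end: ingestion
and filtering of survey records, a hierarchical Bayesian model of catch
per set, posterior before-after differences, and a
credible-interval-overlap decision rule.

## The count model

A gill-net set is one deployment of a standardized net — the sampling
event. Counts are non-negative integers, but fish are not randomly
dispersed: schooling (Yellow Perch) or habitat affinity (Northern Pike)
"clump" catches, so counts are overdispersed relative to a Poisson. The
model used for each lake × species × period group is Poisson-lognormal:

$$y_i \mid \lambda_i \sim \mathrm{Poisson}(\lambda_i), \qquad
  \log \lambda_i \sim \mathrm{Normal}(\mu, \sigma), \qquad i = 1,\dots,n,$$

with priors $\mu \sim N(0, 100)$ and $\sigma \sim U(0, 10)$ by default
(`pln_priors()`). $\sigma$ measures clumping: $\sigma = 0$ is the pure
Poisson limit; at $\sigma = 1$ the variance of counts is roughly
$m + 1.7\,m^2$ for mean $m$. The scientific quantity is the expected
catch for a new net set,

$$M = \exp(\mu + \sigma^2/2),$$

the lognormal population mean (`derived_mean()`). We deliberately use
this model-expected value rather than the average of the realized per-set
means $\exp(\ell_i)$: it is the prediction the model makes for future
effort and is a deterministic function of $(\mu, \sigma)$ per posterior
draw. The finite-population alternative is available via
`fit_pln_group(..., mean_method = "latent")` for sensitivity analysis;
with the group sizes used here (50–200 sets) the two differ negligibly.

## Sampling and diagnostics

`fit_pln_group()` runs a Metropolis-within-Gibbs sampler written as a
small compiled kernel:

* $\mu$ — exact conjugate normal draw given the latent log-means and
  $\sigma$;
* $\sigma$ — random-walk Metropolis on $\log\sigma$ (with Jacobian)
  under the bounded uniform prior;
* each $\ell_i$ — one random-walk Metropolis step per iteration.

Defaults are 3 chains × 30,000 iterations, 5,000 burn-in, thinning 5
(15,000 retained draws), initial step size 0.5 adapted toward a 44%
acceptance rate during burn-in only, so the retained chain is a fixed
kernel. Convergence is summarized by the potential scale reduction
factor (`psrf()`, flag at 1.05) and an autocorrelation-corrected
effective sample size (`ess()`). Every fit is bit-reproducible from
(data, priors, config, seed); groups are fitted on seed substreams
derived by hashing the group key, so adding or removing a group never
perturbs another group's results.

Degenerate inputs are handled explicitly: an all-zero count vector is a
legal fit (posterior mass of $M$ piles up near zero, and the fit is
flagged in `notes`); fewer than two sets is an error; $\sigma = 0$ is
allowed in `derived_mean()` but excluded from the sampler's support.

## The quadrature oracle

`grid_posterior()` is an independent check on the sampler, sharing no
code with it. For each node of a rectangular $(\mu, \sigma)$ grid, the
latent log-mean of each distinct count value is integrated out by 1-D
adaptive quadrature in standardized coordinates (the integrand is
log-concave; its mode is found by Newton iteration and factored out
before integrating). Midpoint rules in both grid directions avoid
special-casing the $\sigma = 0$ boundary, a wide pilot grid is refined
around the posterior mass, and the function refuses to answer (rather
than silently truncating) if mass leaks onto a truncating boundary.

One numerical caveat decided the test design: with only a handful of
observations and the very diffuse default priors, the posterior of
$\sigma$ decays only polynomially while $M$ contains
$\exp(\sigma^2/2)$, so the posterior *mean* of $M$ is dominated by the
upper prior tail of $\sigma$ — a quantity no Monte Carlo method can
estimate stably. Sampler-vs-oracle comparisons therefore use bounded
comparison priors ($\mu \sim N(0,5)$, $\sigma \sim U(0,2)$); this
validates exactly the same code paths. The diffuse defaults are
harmless for real group sizes, where the likelihood dominates.

## Before-after differences and the decision rule

For each lake × species, the Pre (1990–1999) and Post (2005–2014)
period fits are independent; `difference_posterior()` forms draws of
$D = M_{\text{post}} - M_{\text{pre}}$ by pairing retained draws by
index (statistically equivalent to any pairing for independent chains,
but fixed for reproducibility) and summarizes $D$ by its posterior mean
and equal-tailed 95% credible interval (`credible_interval()`,
interpolated percentiles, R quantile type 7 — at these draw counts the
convention is immaterial to reporting precision).

`classify_baci()` then applies the design's decision rule literally,
lake-pairwise, rather than through a single interaction parameter:

* a row's interval *excludes zero* if it is strictly above or below 0
  (closed-interval convention: an endpoint at 0 does not exclude);
* an impact lake is *distinct-from-all-controls* for a species only if
  its difference interval overlaps no control lake's interval (touching
  endpoints count as overlap).

Because conclusions can hinge on which control lake one has — the two
control lakes in the motivating study disagree substantially — the full
per-species lake × lake overlap matrix is attached to every report
(`overlap_matrices()`) and per-control flags are a first-class column,
so the report surfaces what the rule computed rather than a narrative.

No multiple-testing correction is applied across rows, matching the
analysis this package operationalizes; the null-calibration study below
quantifies the per-row false-positive rate instead.

## Data filtering

Three filters mirror standard long-term-survey hygiene, each logging
kept/removed counts (`filter_log()`):

* `filter_consistent_stations()` — sampling locations drift over
  decades; the default `"strict"` rule keeps a station only if it was
  sampled in every year its lake was sampled within 1990–2014. The
  wording "sampled from 1990–2014" is ambiguous; a looser `"periods"`
  mode (present at least once per period) is provided as a config
  switch for comparability.
* `apply_lake_exclusions()` — lake-specific year ranges with known
  protocol problems (defaults: Namakan Lake before 1993, Sand Point
  Lake 1992).
* `assign_periods()` — Pre 1990–1999, Post 2005–2014. The 2000–2004 gap
  encodes a 5-year lag: adults are not recruited to the gear until age
  2–3 and populations respond slowly, so early post-change years would
  dilute any effect. A 2006–2014 after-window is available via
  `period_definition()`.

Exclusions and period labels are row predicates and commute; the
station-consistency filter is *not* a row predicate (its decision
depends on each lake's observed set of years), so the pipeline fixes
the order stations → exclusions → periods.

## The synthetic-data generator

`simulate_study()` generates surveys with exactly the structure the
model assumes: per group, $\ell_i \sim N(\mu, \sigma)$,
$y_i \sim \mathrm{Poisson}(e^{\ell_i})$, laid out as stations × years
(default 10 × 10 per period, matching the scale of the motivating
surveys), with species-level baseline mean catch (defaults 8, 2, 12
fish/set for Walleye, Northern Pike, Yellow Perch, spanning the
sparse-to-abundant range of such surveys) and clumping
$\sigma \in [0.6, 0.9]$. Effects are injected as additive shifts in
mean catch for chosen impact lake × species in the Post period;
$\mu$ is always derived from the requested mean by the lognormal
identity. What the generator does *not* emulate — temporal
autocorrelation, spatial correlation among stations, species
interactions, gear-efficiency drift — is exactly what the fitted model
also ignores, so passing calibration tests demonstrates internal
consistency of the machinery, not robustness to violations a real
survey may contain.

## Validation experiments

The test suite and `scripts/acceptance.R` run (at documented problem
sizes chosen to keep desk-scale runtimes):

* **Oracle agreement** — posterior mean and 95% interval of $M$ from
  the sampler against `grid_posterior()` on a battery of 12 count
  vectors ($n \le 4$, counts $\le 10$), at 2% tolerance.
* **Cross-implementation check** — one group is also fitted with an
  independent general-purpose Gibbs sampler (rjags) under the same
  model and priors.
* **Coverage and bias** — 200 simulated groups ($n = 100$,
  $\mu \in [-1, 2]$, $\sigma \in [0.2, 1.5]$): the 95% interval for
  $M$ should cover truth 90–98% of the time; mean bias of the
  posterior mean of $M$ at $\mu = 1, \sigma = 0.8$ below 5%.
* **Null calibration** — 200 no-effect studies (6 lakes × 1 species ×
  50 sets/period): the zero-exclusion flag should fire at ≈5% of rows
  (binomial tolerance), and distinct-from-all-controls verdicts must be
  rarer still.
* **Effect recovery** — an injected +4 fish/set shift on one impact
  lake at 150 sets/period is recovered in the posterior mean of $D$
  and flagged distinct in the majority of replicates.

## Known limitations

* The model pools sets within a period (no year random effect, no
  covariates, no negative-binomial or zero-inflated alternatives) —
  matching the analysis it implements.
* The decision rule is interval overlap, which is conservative relative
  to a posterior on the interaction contrast itself; it is used because
  it is the rule the motivating analysis reports, and the overlap
  matrix output makes its control-lake sensitivity visible.
* Re-analysis of the original deposited survey records requires those
  records (CSV/XLSX) to be supplied by the user; the package ships only
  the published summary table as reference input.
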