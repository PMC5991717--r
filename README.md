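# bacinet

Before-after/control-impact (BACI) analysis of standardized gill-net
survey counts, with a hierarchical Bayesian Poisson-lognormal model of
catch per net set.

## What it is for

Fisheries agencies run standardized gill-net surveys for decades; catch
per unit effort (CPUE, fish per net set) indexes relative abundance.
When something changes at known sites at a known time — here, the 2000
change to reservoir water-level rules in the Rainy–Namakan lake complex
(MN/ON) — a BACI design compares the before-to-after change in CPUE at
impacted lakes against the change at unaffected control lakes. An
impact is suggested where the before-after change at an impact lake is
distinct from the changes at the controls.

`bacinet` is for analysts running that comparison on per-set count
data: it ingests and filters survey records, fits a Bayesian count
model per lake × species × period, forms posterior before-after
differences, and applies a credible-interval-overlap decision rule —
plus a synthetic-survey generator and an independent quadrature oracle
for validating the whole machinery.

## The model

Counts of fish in a net set are overdispersed ("clumped"). For each
lake × species × period group,

    y_i | lambda_i ~ Poisson(lambda_i),   log lambda_i ~ Normal(mu, sigma)

with diffuse priors `mu ~ N(0, 100)`, `sigma ~ U(0, 10)`. The group
mean catch per set is the lognormal mean `M = exp(mu + sigma^2/2)`,
computed per posterior draw. Fitting is by Metropolis-within-Gibbs
(conjugate draw for `mu`, random-walk updates for `log sigma` and each
latent log-mean) in a compiled kernel; convergence is monitored with
the potential scale reduction factor and effective sample size.

For each lake × species, draws of the before-after effect
`D = M_post − M_pre` are summarized by the posterior mean and an
equal-tailed 95% credible interval. An impact lake is flagged
`distinct-from-all-controls` only when its interval for `D` overlaps no
control lake's interval.

## Worked example

Simulate a six-lake, three-species survey (10 stations × 10 years per
period) with a +5 fish/set Walleye increase injected at Lake
Kabetogama after the change, then run the full pipeline:

```r
library(bacinet)

spec <- study_spec(
  effects = tibble::tibble(lake = "Lake Kabetogama",
                           species = "Walleye", delta = 5),
  seed = 42)
catch <- simulate_study(spec)

report <- catch |>
  filter_consistent_stations() |>
  apply_lake_exclusions() |>
  assign_periods() |>
  fit_catch_groups(config = mcmc_config(chains = 2, iterations = 10000,
                                        burn_in = 2500, thin = 2,
                                        seed = 42)) |>
  baci_differences() |>
  classify_baci(default_lake_roles())

render_baci_table(report[report$species == "Walleye", ], "markdown")
```

| Lake | Species | Difference (95% CrI) | Verdict |
|---|---|---|---|
| Lake Vermilion (C) | Walleye | 0.89 (-0.80 to 2.73) | control |
| Lake of the Woods (C) | Walleye | 0.31 (-1.36 to 1.94) | control |
| Lake Kabetogama | Walleye | 5.57 (3.39 to 7.90) * | distinct-from-all-controls |
| Namakan Lake | Walleye | -2.13 (-4.62 to 0.07) | consistent-with-some-control |
| Rainy Lake | Walleye | 0.47 (-1.53 to 2.68) | consistent-with-some-control |
| Sand Point Lake | Walleye | 0.87 (-0.77 to 2.60) | consistent-with-some-control |

Reading the table: each row is the posterior mean (and 95% credible
interval) of the change in mean catch per net set from 1990–1999 to
2005–2014; `*` marks intervals that exclude zero. Both control lakes
changed by ≈0 (no regional trend was simulated); the injected
Kabetogama increase is recovered (5.57, truth 5) and its interval
overlaps neither control, so it is the one row flagged distinct —
exactly the inference the design is meant to produce. `glance(report)`
confirms: 18 rows, 1 excluding zero, 1 distinct-from-all-controls.

Per-fit summaries are available with `tidy()`/`glance()` on the
elements of `fit_catch_groups()`, interval plots with
`autoplot(report)`, and the full per-species overlap matrices with
`overlap_matrices(report)`. `run_pipeline(run_config(...))` wraps the
same chain and writes posterior draws (CSV), diagnostics (JSON), and
the report (TSV/markdown/JSON), all stamped with seed and config hash;
`inst/cli/bacinet.R` is a thin command-line wrapper.

The published before-after differences for the six study lakes are
shipped as reference input (`published_differences()`); classifying
them reproduces the published significance flags and control-overlap
conclusions, e.g. the Kabetogama Yellow Perch increase (+4.23, CrI
2.93 to 5.57) overlapping neither control lake.

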