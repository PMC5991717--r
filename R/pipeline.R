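#' Fit the Poisson-lognormal model to every lake x species x period group
#'
#' Maps [fit_pln_group()] over the groups of a period-labeled catch
#' table. Each group is fitted on its own RNG substream derived from
#' `config$seed` and the group key, so results for one group do not
#' depend on which other groups are present.
#'
#' @param table a catch table with a `period` column (see
#'   [assign_periods()]).
#' @param priors a [pln_priors()].
#' @param config an [mcmc_config()]; its `seed` is the study seed.
#' @param mean_method passed to [fit_pln_group()].
#' @return a tibble with columns `lake`, `species`, `period`, `n_sets`,
#'   `max_psrf`, `converged`, and a `fit` list column of `pln_fit`
#'   objects. Groups with fewer than 2 sets are dropped with a warning.
#' @export
fit_catch_groups <- function(table, priors = pln_priors(),
                             config = mcmc_config(),
                             mean_method = "lognormal") {
  stopifnot("period" %in% names(table))
  groups <- table |>
    dplyr::group_by(.data$lake, .data$species, .data$period) |>
    dplyr::group_split()
  small <- purrr::map_lgl(groups, ~nrow(.x) < 2)
  if (any(small)) {
    warn(paste0(sum(small), " group(s) with < 2 sets dropped before fitting."))
    groups <- groups[!small]
  }
  purrr::map_dfr(groups, function(g) {
    key <- list(lake = g$lake[1], species = g$species[1],
                period = as.character(g$period[1]))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, key$lake, key$species, key$period)
    fit <- fit_pln_group(g$count, priors = priors, config = cfg,
                         group = key, mean_method = mean_method)
    tibble::tibble(lake = key$lake, species = key$species,
                   period = key$period, n_sets = nrow(g),
                   max_psrf = max(fit$diagnostics$psrf),
                   converged = max(fit$diagnostics$psrf) <= 1.05,
                   fit = list(fit))
  })
}

#' Before-after difference summaries for every lake x species
#'
#' Pairs each lake x species' Post fit with its Pre fit via
#' [difference_posterior()]. Combinations missing either period are
#' skipped with a warning.
#'
#' @param fits output of [fit_catch_groups()].
#' @param level credible level.
#' @return a tibble of difference summaries, one row per lake x species.
#' @export
baci_differences <- function(fits, level = 0.95) {
  keys <- fits |> dplyr::distinct(.data$lake, .data$species)
  purrr::pmap_dfr(keys, function(lake, species) {
    pre <- fits$fit[fits$lake == lake & fits$species == species &
                      fits$period == "Pre"]
    post <- fits$fit[fits$lake == lake & fits$species == species &
                       fits$period == "Post"]
    if (length(pre) != 1 || length(post) != 1) {
      warn(paste0("Skipping ", lake, " / ", species,
                  ": missing a period fit."))
      return(NULL)
    }
    difference_posterior(post[[1]], pre[[1]], level = level)
  })
}

#' Assemble a full-run configuration
#'
#' @param input path to a catch-record file (CSV/TSV/XLSX), or a data
#'   frame already in memory.
#' @param schema optional column mapping for [read_catch_table()].
#' @param roles lake role map; defaults to [default_lake_roles()].
#' @param station_mode station-consistency rule, see
#'   [filter_consistent_stations()].
#' @param exclusions lake exclusion rules, see [apply_lake_exclusions()].
#' @param periods a [period_definition()].
#' @param priors a [pln_priors()].
#' @param mcmc an [mcmc_config()].
#' @param seed overrides `mcmc$seed` when non-NULL.
#' @param out_dir directory for artifacts; `NULL` writes nothing.
#' @param allow_unconverged keep going (and exit cleanly) when a group
#'   fails the PSRF check.
#' @param level credible level for all intervals.
#' @return a `run_config` list.
#' @export
run_config <- function(input, schema = NULL, roles = default_lake_roles(),
                       station_mode = "strict",
                       exclusions = default_lake_exclusions(),
                       periods = period_definition(),
                       priors = pln_priors(), mcmc = mcmc_config(),
                       seed = NULL, out_dir = NULL,
                       allow_unconverged = FALSE, level = 0.95) {
  if (!is.null(seed)) mcmc$seed <- as.integer(seed)
  structure(list(input = input, schema = schema, roles = roles,
                 station_mode = station_mode, exclusions = exclusions,
                 periods = periods, priors = priors, mcmc = mcmc,
                 out_dir = out_dir,
                 allow_unconverged = isTRUE(allow_unconverged),
                 level = level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `input`, `schema` (map), `roles` (map),
#' `station_mode`, `exclusions` (list of `{lake, year_min, year_max}`),
#' `periods` (`before`/`after` year pairs), `priors`
#' (`mu_mean`/`mu_sd`/`sigma_upper`), `mcmc` (fields of
#' [mcmc_config()]), `seed`, `out_dir`, `allow_unconverged`, `level`.
#' Omitted keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "bacinet_io_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$input)) {
    abort("Config must name an `input` file.", class = "bacinet_schema_error")
  }
  run_config(
    input = y$input,
    schema = if (!is.null(y$schema)) unlist(y$schema),
    roles = if (is.null(y$roles)) default_lake_roles() else unlist(y$roles),
    station_mode = y$station_mode %||% "strict",
    exclusions = if (is.null(y$exclusions)) default_lake_exclusions() else
      dplyr::bind_rows(y$exclusions),
    periods = if (is.null(y$periods)) period_definition() else
      period_definition(unlist(y$periods$before), unlist(y$periods$after)),
    priors = if (is.null(y$priors)) pln_priors() else
      do.call(pln_priors, y$priors),
    mcmc = if (is.null(y$mcmc)) mcmc_config() else
      do.call(mcmc_config, y$mcmc),
    seed = y$seed, out_dir = y$out_dir,
    allow_unconverged = isTRUE(y$allow_unconverged),
    level = y$level %||% 0.95)
}

#' Run the full BACI analysis pipeline
#'
#' Executes read -> station filter -> lake exclusions -> period labels ->
#' per-group Poisson-lognormal fits -> before-after differences ->
#' control-overlap classification -> rendering. When `out_dir` is set,
#' writes the canonical filtered CSV, the filter log, pooled posterior
#' draws (CSV), per-group diagnostics (JSON), the report as TSV, markdown
#' and JSON -- every artifact stamped with the package version, seed and
#' a hash of the configuration, so a run is reproducible from
#' (input, config) alone.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return the `baci_report`, invisibly carrying `fits` and `table`
#'   attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))

  table <- if (is.data.frame(config$input)) {
    as_catch_table(config$input, schema = config$schema)
  } else {
    read_catch_table(config$input, schema = config$schema)
  }
  table <- table |>
    filter_consistent_stations(mode = config$station_mode,
                               periods = config$periods) |>
    apply_lake_exclusions(rules = config$exclusions) |>
    assign_periods(periods = config$periods)

  fits <- fit_catch_groups(table, priors = config$priors,
                           config = config$mcmc)
  diffs <- baci_differences(fits, level = config$level)
  report <- classify_baci(diffs, roles = config$roles)

  meta <- list(package = "bacinet",
               version = as.character(utils::packageVersion("bacinet")),
               seed = config$mcmc$seed,
               config_hash = rlang::hash(config[setdiff(names(config),
                                                        "out_dir")]),
               priors = unlist(config$priors))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_catch_table(table, file.path(config$out_dir, "filtered_catch.csv"))
    writeLines(filter_log(table), file.path(config$out_dir, "filter_log.txt"))
    draws <- purrr::pmap_dfr(fits, function(lake, species, period, fit, ...) {
      dplyr::mutate(fit$draws, lake = lake, species = species,
                    period = period, .before = 1)
    })
    readr::write_csv(draws, file.path(config$out_dir, "posterior_draws.csv"),
                     progress = FALSE)
    diag <- purrr::pmap(fits, function(lake, species, period, fit, ...) {
      list(lake = lake, species = species, period = period,
           n_sets = length(fit$counts), diagnostics = fit$diagnostics,
           accept = as.data.frame(fit$accept), notes = fit$notes)
    })
    jsonlite::write_json(list(meta = meta, groups = diag),
                         file.path(config$out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(render_baci_table(report, "tsv", metadata = meta),
               file.path(config$out_dir, "report.tsv"))
    writeLines(render_baci_table(report, "markdown", metadata = meta),
               file.path(config$out_dir, "report.md"))
    jsonlite::write_json(
      list(meta = meta,
           rows = dplyr::select(as.data.frame(report), -"overlaps_controls"),
           overlap = lapply(overlap_matrices(report), function(m)
             as.data.frame(m)),
           per_control = purrr::map(seq_len(nrow(report)), function(i)
             as.list(report$overlaps_controls[[i]]))),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  if (!config$allow_unconverged && any(!fits$converged)) {
    bad <- fits[!fits$converged, c("lake", "species", "period", "max_psrf")]
    abort(paste0("Convergence failure (psrf > 1.05) in ", nrow(bad),
                 " group(s): ",
                 paste(bad$lake, bad$species, bad$period, collapse = "; ")),
          class = "bacinet_convergence_error")
  }
  attr(report, "fits") <- fits
  attr(report, "table") <- table
  attr(report, "meta") <- meta
  invisible(report)
}

#' Simulate a survey table from a YAML study specification and write CSV
#'
#' The YAML may set any argument of [study_spec()] (`lakes`, `roles`,
#' `species`, `base_mean`, `sigma`, `effects`, `drift`, `n_stations`,
#' `n_years`, `seed`).
#'
#' @param spec_path YAML file describing the study, or a `study_spec`.
#' @param out_path output CSV path.
#' @return the simulated catch table, invisibly.
#' @export
simulate_command <- function(spec_path, out_path) {
  spec <- if (inherits(spec_path, "study_spec")) spec_path else {
    if (!file.exists(spec_path)) {
      abort(paste0("Spec file not found: ", spec_path),
            class = "bacinet_io_error")
    }
    y <- yaml::read_yaml(spec_path)
    args <- list()
    for (k in c("lakes", "species", "drift", "n_stations", "n_years",
                "seed")) {
      if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
    }
    for (k in c("roles", "base_mean", "sigma")) {
      if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
    }
    if (!is.null(y$effects)) args$effects <- dplyr::bind_rows(y$effects)
    bad <- setdiff(names(y), c(names(args), "effects"))
    if (length(bad)) {
      abort(paste0("Unknown study-spec field(s): ",
                   paste(bad, collapse = ", ")),
            class = "bacinet_schema_error")
    }
    do.call(study_spec, args)
  }
  tab <- simulate_study(spec)
  write_catch_table(tab, out_path)
  inform(paste0("Wrote ", nrow(tab), " records (",
                dplyr::n_distinct(tab$lake), " lakes, ",
                dplyr::n_distinct(tab$species), " species) to ", out_path))
  invisible(tab)
}

#' Published before-after differences for the six study lakes
#'
#' Posterior summaries (difference in mean catch per gill-net set,
#' Pre-2000 vs Post-2005, with equal-tailed 95% credible intervals) as
#' published for the original 1990-2014 Minnesota large-lake gill-net
#' analysis. Shipped as reference input for the interval-overlap
#' decision logic and for comparing a re-analysis of the deposited
#' survey data against the published table.
#'
#' @return a tibble with columns `lake`, `species`, `post_mean`,
#'   `ci_low`, `ci_high`.
#' @export
published_differences <- function() {
  path <- system.file("extdata", "published_differences.tsv",
                      package = "bacinet")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
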