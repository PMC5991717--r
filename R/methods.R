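#' @export
print.pln_fit <- function(x, ...) {
  grp <- if (!is.null(x$group))
    paste0(" [", paste(unlist(x$group), collapse = " / "), "]") else ""
  cat("Poisson-lognormal group fit", grp, "\n", sep = "")
  cat("  sets:", length(x$counts), " retained draws:", nrow(x$draws),
      "(", x$config$chains, "chains )\n")
  s <- tidy(x)
  cat(sprintf("  %-6s %8.3f  [%.3f, %.3f]\n", s$term, s$estimate,
              s$conf.low, s$conf.high), sep = "")
  cat("  max psrf:", sprintf("%.3f", max(x$diagnostics$psrf)),
      " min ess:", round(min(x$diagnostics$ess)), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy posterior summaries of a Poisson-lognormal fit
#'
#' @param x a `pln_fit`.
#' @param level credible level.
#' @param ... unused.
#' @return a tibble with one row per parameter (`mu`, `sigma`, `M`):
#'   posterior mean, sd, and equal-tailed interval.
#' @method tidy pln_fit
#' @export
tidy.pln_fit <- function(x, level = 0.95, ...) {
  purrr::map_dfr(c("mu", "sigma", "M"), function(p) {
    d <- x$draws[[p]]
    ci <- credible_interval(d, level)
    tibble::tibble(term = p, estimate = mean(d), std.error = sd(d),
                   conf.low = ci[1], conf.high = ci[2])
  })
}

#' One-row fit summary
#'
#' @param x a `pln_fit`.
#' @param ... unused.
#' @return a tibble: group labels, sizes, diagnostics, posterior mean
#'   catch.
#' @method glance pln_fit
#' @export
glance.pln_fit <- function(x, ...) {
  tibble::tibble(
    lake = x$group$lake %||% NA_character_,
    species = x$group$species %||% NA_character_,
    period = x$group$period %||% NA_character_,
    n_sets = length(x$counts), n_draws = nrow(x$draws),
    chains = x$config$chains,
    mean_catch = mean(x$draws$M),
    max_psrf = max(x$diagnostics$psrf),
    min_ess = min(x$diagnostics$ess))
}

#' @export
print.baci_report <- function(x, ...) {
  cat(render_baci_table(x, "markdown"), "\n")
  invisible(x)
}

#' Flatten a BACI report to a plain tibble
#'
#' Expands the per-control overlap flags into one logical column per
#' control lake (`overlaps_<lake>`).
#'
#' @param x a `baci_report`.
#' @param ... unused.
#' @return a tibble without list columns.
#' @method tidy baci_report
#' @export
tidy.baci_report <- function(x, ...) {
  flat <- tibble::as_tibble(x[setdiff(names(x), "overlaps_controls")])
  ctrl <- unique(unlist(purrr::map(x$overlaps_controls, names)))
  for (cl in ctrl) {
    flat[[paste0("overlaps_", gsub("[^A-Za-z0-9]+", "_", cl))]] <-
      purrr::map_lgl(x$overlaps_controls, ~.x[cl] %||% NA)
  }
  flat
}

#' One-row summary of a BACI report
#'
#' @param x a `baci_report`.
#' @param ... unused.
#' @return a tibble with row counts by verdict and zero-exclusion.
#' @method glance baci_report
#' @export
glance.baci_report <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_species = dplyr::n_distinct(x$species),
    n_excludes_zero = sum(x$excludes_zero),
    n_distinct_from_controls = sum(x$verdict == "distinct-from-all-controls"),
    n_indeterminate = sum(x$verdict == "indeterminate"))
}

#' Posterior density of the group mean catch
#'
#' @param object a `pln_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pln_fit
#' @export
autoplot.pln_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$M)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "Mean catch per gill-net set",
                  y = "Posterior density",
                  title = paste(unlist(object$group), collapse = " / ")) +
    ggplot2::theme_minimal()
}

#' Interval plot of before-after differences by lake and species
#'
#' One point-range per lake (posterior mean and 95% interval of the
#' Post minus Pre difference in mean catch per set), faceted by species,
#' controls distinguished by color, with a dashed reference line at
#' zero.
#'
#' @param object a `baci_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot baci_report
#' @export
autoplot.baci_report <- function(object, ...) {
  df <- tibble::as_tibble(object[setdiff(names(object),
                                         "overlaps_controls")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lake, y = .data$post_mean,
                                   ymin = .data$ci_low,
                                   ymax = .data$ci_high,
                                   color = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~species, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Difference in mean catch per set (Post - Pre)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
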