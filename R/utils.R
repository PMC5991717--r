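# internal helpers shared across the package

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Retrieve the filter log attached to a catch table
#'
#' Each filtering verb ([filter_consistent_stations()],
#' [apply_lake_exclusions()], [assign_periods()]) appends one entry per
#' decision it makes (records kept, records removed, and why) to a log
#' carried on the table as an attribute. The log travels with the table
#' through the pipeline and ends up in the run artifacts.
#'
#' @param table a catch table, as returned by [read_catch_table()] or any
#'   filtering verb.
#' @return a character vector of log lines (possibly empty).
#' @export
filter_log <- function(table) {
  attr(table, "filter_log") %||% character(0)
}

append_filter_log <- function(table, lines) {
  attr(table, "filter_log") <- c(filter_log(table), lines)
  table
}

carry_log <- function(new, old, lines = character(0)) {
  attr(new, "filter_log") <- c(filter_log(old), lines)
  attr(new, "provenance") <- attr(old, "provenance")
  new
}

# Stable per-group seed derivation: a polynomial hash of the group key is
# folded into the study seed, so each (lake, species, period) owns an RNG
# substream and adding or removing other groups never perturbs it.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

`%||%` <- rlang::`%||%`
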