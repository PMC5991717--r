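#' Define the before and after sampling periods
#'
#' The before-after contrast needs two disjoint blocks of survey years. The
#' defaults encode a 5-year lag after the management change: the before
#' period is 1990-1999 and the after period 2005-2014, leaving 2000-2004
#' unassigned. An alternative after-window (for example 2006-2014) can be
#' supplied.
#'
#' @param before integer vector of length 2, inclusive year range of the
#'   "Pre" period.
#' @param after integer vector of length 2, inclusive year range of the
#'   "Post" period.
#' @return a `period_definition` list with elements `before` and `after`.
#' @examples
#' period_definition()
#' period_definition(after = c(2006, 2014))
#' @export
period_definition <- function(before = c(1990L, 1999L), after = c(2005L, 2014L)) {
  before <- as.integer(before); after <- as.integer(after)
  stopifnot(length(before) == 2, length(after) == 2,
            before[1] <= before[2], after[1] <= after[2])
  if (before[2] >= after[1]) {
    abort("`before` must end strictly before `after` begins.",
          class = "bacinet_validation_error")
  }
  structure(list(before = before, after = after), class = "period_definition")
}

#' Default lake-specific year exclusions
#'
#' Long-term survey series sometimes carry early years collected under a
#' different or incompletely documented protocol. The default rules drop
#' Namakan Lake records before 1993 (methodology change) and Sand Point
#' Lake 1992 (no usable data). Each rule is an inclusive year range for one
#' lake.
#'
#' @return a tibble with columns `lake`, `year_min`, `year_max`.
#' @export
default_lake_exclusions <- function() {
  tibble::tribble(
    ~lake,             ~year_min, ~year_max,
    "Namakan Lake",        1990L,     1992L,
    "Sand Point Lake",     1992L,     1992L
  )
}

#' Default control/impact roles for the study lakes
#'
#' Water-level management changed in 2000 for the Namakan reservoir complex
#' and (more subtly) Rainy Lake; Lake of the Woods and Lake Vermilion are
#' unaffected reference systems.
#'
#' @return a named character vector mapping lake name to `"control"` or
#'   `"impact"`.
#' @export
default_lake_roles <- function() {
  c("Lake of the Woods" = "control",
    "Lake Vermilion"    = "control",
    "Lake Kabetogama"   = "impact",
    "Namakan Lake"      = "impact",
    "Rainy Lake"        = "impact",
    "Sand Point Lake"   = "impact")
}

canonical_cols <- c("lake", "station", "year", "species", "count")

validate_catch_records <- function(df, source = "data") {
  for (col in canonical_cols) {
    if (!col %in% names(df)) {
      abort(paste0("Required column `", col, "` is missing from ", source, "."),
            class = "bacinet_schema_error")
    }
  }
  df$year <- as.integer(df$year)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0) {
    abort(paste0("`count` must be a non-negative integer; offending row(s): ",
                 paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5) " ..." else "", "."),
          class = "bacinet_validation_error")
  }
  df$count <- as.integer(cnt)
  bad_year <- which(is.na(df$year))
  if (length(bad_year) > 0) {
    abort(paste0("`year` must be an integer year; offending row(s): ",
                 paste(head(bad_year, 5L), collapse = ", "), "."),
          class = "bacinet_validation_error")
  }
  df
}

#' Coerce a data frame of gill-net records to a canonical catch table
#'
#' One row is one gill-net set for one species: `lake`, `station`, `year`,
#' `species`, `count`. A `set` index is added within each
#' (lake, station, year, species) cell when absent, so that every row --
#' every individual net set -- has a unique key. Counts must be
#' non-negative integers.
#'
#' @param df a data frame.
#' @param schema optional named character vector mapping canonical column
#'   names (`lake`, `station`, `year`, `species`, `count`, optionally
#'   `set`) to the column names used in `df`, e.g.
#'   `c(lake = "WATERBODY", count = "N")`.
#' @param source label recorded in the provenance attribute.
#' @return a tibble of validated records with attributes `provenance` and
#'   `filter_log`.
#' @export
as_catch_table <- function(df, schema = NULL, source = "data.frame") {
  df <- tibble::as_tibble(df)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        abort(paste0("Schema maps `", canon, "` to column `", src,
                     "`, which is not present."),
              class = "bacinet_schema_error")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  df <- validate_catch_records(df, source = source)
  if (!"set" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$lake, .data$station, .data$year, .data$species) |>
      dplyr::mutate(set = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  keep <- c("lake", "station", "year", "species", "set", "count",
            intersect("role", names(df)))
  out <- df[, keep]
  key <- paste(out$lake, out$station, out$year, out$species, out$set)
  if (anyDuplicated(key)) {
    abort("Duplicate (lake, station, year, species, set) keys in input.",
          class = "bacinet_validation_error")
  }
  attr(out, "provenance") <- source
  attr(out, "filter_log") <-
    paste0("ingest: ", nrow(out), " records from ", source)
  out
}

#' Read gill-net catch records from a delimited or spreadsheet file
#'
#' Reads a CSV/TSV file (or an `.xlsx` sheet when the readxl package is
#' available), applies an optional column-name mapping, validates the
#' records and returns a canonical catch table. Row count is preserved:
#' this function only ingests, it never filters.
#'
#' @param path path to the input file.
#' @param schema optional column mapping, see [as_catch_table()].
#' @param sheet sheet name or index for spreadsheet input.
#' @return a catch table (tibble); see [as_catch_table()].
#' @export
read_catch_table <- function(path, schema = NULL, sheet = 1) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path), class = "bacinet_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading spreadsheets requires the readxl package; convert to CSV.",
            class = "bacinet_io_error")
    }
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_delim(path, delim = if (ext == "tsv") "\t" else ",",
                      show_col_types = FALSE, progress = FALSE)
  }
  as_catch_table(df, schema = schema, source = path)
}

#' Write a catch table to canonical CSV
#'
#' @param table a catch table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catch_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Keep only stations sampled consistently across the study window
#'
#' Sampling locations drift over decades; comparing periods is only fair
#' for stations with an unbroken series. Under the default `"strict"` rule
#' a (lake, station) is retained only if it appears in every year in which
#' that lake was sampled inside `window`. The looser `"periods"` rule
#' retains stations sampled in at least one year of each period, trading
#' strict comparability for sample size.
#'
#' @param table a catch table.
#' @param mode `"strict"` (default) or `"periods"`.
#' @param window inclusive year range defining the study window.
#' @param periods a [period_definition()], used by the `"periods"` rule.
#' @return the filtered catch table; removals are appended to the filter
#'   log (see [filter_log()]). An empty result raises a warning, not an
#'   error.
#' @export
filter_consistent_stations <- function(table,
                                       mode = c("strict", "periods"),
                                       window = c(1990L, 2014L),
                                       periods = period_definition()) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) {
    abort("Catch table is empty.", class = "bacinet_validation_error")
  }
  in_window <- table$year >= window[1] & table$year <= window[2]
  wtab <- table[in_window, ]
  keep_key <- if (mode == "strict") {
    lake_years <- wtab |>
      dplyr::distinct(.data$lake, .data$year) |>
      dplyr::count(.data$lake, name = "n_lake_years")
    wtab |>
      dplyr::distinct(.data$lake, .data$station, .data$year) |>
      dplyr::count(.data$lake, .data$station, name = "n_station_years") |>
      dplyr::inner_join(lake_years, by = "lake") |>
      dplyr::filter(.data$n_station_years == .data$n_lake_years)
  } else {
    wtab |>
      dplyr::distinct(.data$lake, .data$station, .data$year) |>
      dplyr::group_by(.data$lake, .data$station) |>
      dplyr::summarise(
        in_before = any(.data$year >= periods$before[1] &
                          .data$year <= periods$before[2]),
        in_after = any(.data$year >= periods$after[1] &
                         .data$year <= periods$after[2]),
        .groups = "drop") |>
      dplyr::filter(.data$in_before & .data$in_after)
  }
  keep <- paste(table$lake, table$station) %in%
    paste(keep_key$lake, keep_key$station)
  out <- table[keep, ]
  dropped <- table |>
    dplyr::filter(!keep) |>
    dplyr::distinct(.data$lake, .data$station)
  line <- paste0("filter_consistent_stations(", mode, "): kept=", nrow(out),
                 " removed=", sum(!keep), " stations_dropped=",
                 paste(paste0(dropped$lake, "/", dropped$station),
                       collapse = ";"))
  if (nrow(out) == 0) {
    warn("All records removed by the station-consistency filter.")
  }
  carry_log(out, table, line)
}

#' Remove lake-specific excluded year ranges
#'
#' @param table a catch table.
#' @param rules a tibble with columns `lake`, `year_min`, `year_max`
#'   (inclusive), one row per exclusion; defaults to
#'   [default_lake_exclusions()]. Rules naming lakes absent from the table
#'   are logged and ignored; an empty rule set is a no-op.
#' @return the filtered catch table with removals logged.
#' @export
apply_lake_exclusions <- function(table, rules = default_lake_exclusions()) {
  if (is.null(rules) || nrow(rules) == 0) {
    return(append_filter_log(table, "apply_lake_exclusions: kept=all removed=0 (no rules)"))
  }
  lines <- character(0)
  drop <- rep(FALSE, nrow(table))
  for (k in seq_len(nrow(rules))) {
    r <- rules[k, ]
    if (!r$lake %in% table$lake) {
      lines <- c(lines, paste0("apply_lake_exclusions: rule for absent lake `",
                               r$lake, "` ignored removed=0"))
      next
    }
    hit <- table$lake == r$lake & table$year >= r$year_min &
      table$year <= r$year_max
    drop <- drop | hit
    lines <- c(lines, paste0("apply_lake_exclusions: ", r$lake, " ",
                             r$year_min, "-", r$year_max,
                             " removed=", sum(hit)))
  }
  out <- table[!drop, ]
  lines <- c(lines, paste0("apply_lake_exclusions: kept=", nrow(out),
                           " removed=", sum(drop)))
  carry_log(out, table, lines)
}

#' Label records with their study period
#'
#' Adds a `period` column (`"Pre"` / `"Post"`); records whose year falls in
#' neither range -- the lag years between the periods under the defaults --
#' are dropped and counted in the filter log.
#'
#' @param table a catch table.
#' @param periods a [period_definition()].
#' @return the labeled catch table.
#' @export
assign_periods <- function(table, periods = period_definition()) {
  stopifnot(inherits(periods, "period_definition"))
  period <- dplyr::case_when(
    table$year >= periods$before[1] & table$year <= periods$before[2] ~ "Pre",
    table$year >= periods$after[1] & table$year <= periods$after[2] ~ "Post",
    TRUE ~ NA_character_
  )
  out <- table
  out$period <- factor(period, levels = c("Pre", "Post"))
  dropped <- is.na(period)
  out <- out[!dropped, ]
  line <- paste0("assign_periods: kept=", nrow(out), " removed=",
                 sum(dropped), " (outside ",
                 periods$before[1], "-", periods$before[2], " and ",
                 periods$after[1], "-", periods$after[2], ")",
                 " pre=", sum(period == "Pre", na.rm = TRUE),
                 " post=", sum(period == "Post", na.rm = TRUE))
  carry_log(out, table, line)
}
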