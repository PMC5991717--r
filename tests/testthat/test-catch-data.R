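test_that("ingestion preserves rows, maps schemas, and validates counts", {
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(toy_catch(), tf)
  tab <- read_catch_table(tf)
  expect_equal(nrow(tab), 3)
  expect_setequal(c("lake", "station", "year", "species", "set", "count"),
                  setdiff(names(tab), "role"))
  # two sets in the same lake/station/year/species cell get distinct ids
  expect_equal(tab$set[1:2], c(1L, 2L))
  expect_match(attr(tab, "provenance"), "\\.csv$")

  # schema mapping
  renamed <- dplyr::rename(toy_catch(), WATER = lake, N = count)
  tab2 <- as_catch_table(renamed, schema = c(lake = "WATER", count = "N"))
  expect_equal(tab2$count, tab$count)

  # contract violations
  bad <- toy_catch()
  bad$count[2] <- -1L
  expect_error(as_catch_table(bad), "row\\(s\\): 2",
               class = "bacinet_validation_error")
  expect_error(as_catch_table(dplyr::select(toy_catch(), -species)),
               "`species`", class = "bacinet_schema_error")
  expect_error(as_catch_table(toy_catch(),
                              schema = c(count = "nope")),
               "nope", class = "bacinet_schema_error")
  expect_error(read_catch_table("no/such/file.csv"),
               class = "bacinet_io_error")
})

test_that("station-consistency filter keeps only stations present in every sampled year", {
  # station B misses 1997: all of B goes, A stays
  full <- grid_catch(stations = "A", years = 1990:2014)
  partial <- grid_catch(stations = "B", years = setdiff(1990:2014, 1997))
  tab <- as_catch_table(dplyr::bind_rows(full, partial))
  out <- filter_consistent_stations(tab)
  expect_setequal(unique(out$station), "A")
  expect_equal(nrow(out), 25)

  # identity when every station is complete
  tab2 <- as_catch_table(grid_catch(stations = c("A", "B")))
  out2 <- filter_consistent_stations(tab2)
  expect_equal(as.data.frame(out2), as.data.frame(tab2),
               ignore_attr = TRUE)

  # empty result warns rather than errors
  gappy <- dplyr::bind_rows(
    grid_catch(stations = "A", years = c(1990, 1992)),
    grid_catch(stations = "B", years = c(1991, 1992)))
  expect_warning(res <- filter_consistent_stations(as_catch_table(gappy)),
                 "All records removed")
  expect_equal(nrow(res), 0)
})

test_that("station filter agrees with a brute-force per-station year scan", {
  # drop ~10% of station-years from a complete grid, then compare against
  # an independently coded recount
  base <- grid_catch(lakes = c("L1", "L2"), stations = c("A", "B", "C"),
                     years = 1990:2014)
  set.seed(42)
  keep <- runif(nrow(base)) > 0.1
  tab <- as_catch_table(base[keep, ])
  out <- filter_consistent_stations(tab)

  expected <- 0L
  for (lk in unique(tab$lake)) {
    sub <- tab[tab$lake == lk, ]
    lake_years <- sort(unique(sub$year))
    for (st in unique(sub$station)) {
      st_years <- sort(unique(sub$year[sub$station == st]))
      if (identical(st_years, lake_years)) {
        expected <- expected + sum(sub$station == st)
      }
    }
  }
  expect_equal(nrow(out), expected)
})

test_that("periods mode retains stations sampled at least once per period", {
  tab <- as_catch_table(dplyr::bind_rows(
    grid_catch(stations = "A", years = c(1991, 2007)),
    grid_catch(stations = "B", years = c(1991, 1995)),   # never in Post
    grid_catch(stations = "C", years = 1990:2014)))
  out <- filter_consistent_stations(tab, mode = "periods")
  expect_setequal(unique(out$station), c("A", "C"))
})

test_that("lake exclusions remove exactly the matching records", {
  tab <- as_catch_table(grid_catch(lakes = c("Namakan Lake", "LakeX"),
                                   years = 1990:1996))
  out <- apply_lake_exclusions(tab)
  expect_false(any(out$lake == "Namakan Lake" & out$year < 1993))
  expect_equal(sum(out$lake == "Namakan Lake"), 2 * 4)  # 1993-1996 survive
  expect_equal(sum(out$lake == "LakeX"), 2 * 7)         # untouched

  # explicit toy rule
  rule <- tibble::tibble(lake = "LakeX", year_min = 1995L, year_max = 1995L)
  out2 <- apply_lake_exclusions(tab, rules = rule)
  expect_equal(nrow(tab) - nrow(out2), sum(tab$lake == "LakeX" &
                                             tab$year == 1995))

  # empty rules: identity; absent lake: logged no-op
  expect_equal(nrow(apply_lake_exclusions(tab, rules = NULL)), nrow(tab))
  out3 <- apply_lake_exclusions(tab, rules = tibble::tibble(
    lake = "Atlantis", year_min = 1990L, year_max = 2000L))
  expect_equal(nrow(out3), nrow(tab))
  expect_match(paste(filter_log(out3), collapse = "\n"), "Atlantis")
})

test_that("period labels follow the before/lag/after windows", {
  tab <- as_catch_table(grid_catch(stations = "A",
                                   years = c(1999, 2002, 2005)))
  out <- assign_periods(tab)
  expect_equal(as.character(out$period[order(out$year)]), c("Pre", "Post"))
  expect_false(2002 %in% out$year)

  # all inside the before range
  tab2 <- as_catch_table(grid_catch(years = 1991:1995))
  expect_true(all(assign_periods(tab2)$period == "Pre"))

  # random years vs brute-force membership recount
  tab3 <- as_catch_table(random_catch(seed = 7))
  out3 <- assign_periods(tab3)
  expected <- sum(tab3$year %in% c(1990:1999, 2005:2014))
  expect_equal(nrow(out3), expected)

  # alternative after-window via config
  pd <- period_definition(after = c(2006, 2014))
  expect_false(2005 %in% assign_periods(tab, pd)$year)
  expect_error(period_definition(before = c(1990, 2006), after = c(2005, 2014)),
               class = "bacinet_validation_error")
})

test_that("filters are idempotent, commute, and conserve record counts", {
  for (seed in 1:4) {
    # structured survey with sparse random dropout of station-years
    base <- grid_catch(lakes = c("L1", "L2"), stations = c("A", "B", "C"),
                       years = 1990:2014)
    keep <- withr::with_seed(seed, runif(nrow(base)) > 0.02)
    tab <- as_catch_table(base[keep, ])

    f1 <- suppressWarnings(filter_consistent_stations(tab))
    if (nrow(f1) > 0) {
      expect_equal(as.data.frame(filter_consistent_stations(f1)),
                   as.data.frame(f1), ignore_attr = TRUE)
    }
    rule <- tibble::tibble(lake = "L1", year_min = 1995L, year_max = 1999L)
    e1 <- apply_lake_exclusions(tab, rules = rule)
    expect_equal(as.data.frame(apply_lake_exclusions(e1, rules = rule)),
                 as.data.frame(e1), ignore_attr = TRUE)
    p1 <- assign_periods(tab)
    expect_equal(as.data.frame(assign_periods(p1)), as.data.frame(p1),
                 ignore_attr = TRUE)

    # commutation of exclusions and period labels (both row predicates)
    ab <- assign_periods(apply_lake_exclusions(tab, rules = rule))
    ba <- apply_lake_exclusions(assign_periods(tab), rules = rule)
    expect_equal(as.data.frame(ab), as.data.frame(ba), ignore_attr = TRUE)

    # conservation: kept + removed = input, as recorded in the log
    out <- apply_lake_exclusions(tab, rules = tibble::tibble(
      lake = "L2", year_min = 1990L, year_max = 2014L))
    removed <- sum(as.integer(sub(".*removed=(\\d+).*", "\\1",
                                  grep("L2 1990-2014",
                                       filter_log(out), value = TRUE))))
    expect_equal(nrow(out) + removed, nrow(tab))
  }
})
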