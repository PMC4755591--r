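test_that("panel files read with validation, blank cells as zero", {
  p1 <- table1_panel()
  expect_s3_class(p1, "traffic_panel")
  expect_equal(length(panel_regions(p1)), 10L)
  expect_equal(panel_years(p1), 2012L)
  expect_equal(p1$ships[p1$region == SGP], 1410)

  # blanks printed for zero-traffic cells parse as 0
  p2 <- table2_panel()
  expect_equal(p2$cargo_flights[p2$region == TAIWAN], 0)
  expect_equal(p2$passenger_flights[p2$region == SHANDONG], 0)

  # header-only file gives an empty panel
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("region,year,passenger_flights,cargo_flights,ships", f)
  expect_equal(nrow(read_panel(f)), 0L)

  # invalid counts are named by row; duplicates rejected
  writeLines(c("region,year,passenger_flights,cargo_flights,ships",
               "A,2000,5,1,2", "B,2000,-3,0,0"), f)
  expect_error(read_panel(f), "row 2")
  writeLines(c("region,year,passenger_flights,cargo_flights,ships",
               "A,2000,5,1,2", "A,2000,1,0,0"), f)
  expect_error(read_panel(f), "duplicate")
  writeLines(c("region,year,passenger_flights,cargo_flights,ships",
               "A,2000,2.5,1,2"), f)
  expect_error(read_panel(f), "integer")
})

test_that("comma and tab dialects are auto-detected and round-trip", {
  p1 <- table1_panel()
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p1, fc, dialect = "comma")
  write_panel(p1, ft, dialect = "tab")
  expect_equal(read_panel(fc), p1)
  expect_equal(read_panel(ft), p1)
})

test_that("region labels are canonical and deterministically ordered", {
  expect_equal(region_label("New Zealand", "North Island"), NZN)
  expect_equal(region_label("Singapore", ""), SGP)
  expect_equal(region_label("Singapore", NA), SGP)
  expect_error(region_label(""), "non-empty")
  # label ordering is byte-wise, independent of locale
  labs <- c("b", "A", "a—x", "a")
  expect_equal(sort_regions(labs), labs[order(labs, method = "radix")])
})

make_map <- function() {
  port_region_map(data.frame(
    port = c("LHR", "SIN", "AKL", "POM"),
    country = c("United Kingdom", "Singapore", "New Zealand",
                "Papua New Guinea"),
    subdivision = c("England", "", "North Island", "National Capital District"),
    stringsAsFactors = FALSE))
}

test_that("itinerary attribution follows last-port and proportional rules", {
  pm <- make_map()
  # multi-stop: all weight on the final foreign stop's region ...
  expect_equal(attribute_itinerary(c("LHR", "SIN", "SYD"), 1, pm, "last_port"),
               c(Singapore = 1.0))
  # ... or split equally over the foreign stops
  expect_equal(attribute_itinerary(c("LHR", "SIN", "SYD"), 1, pm, "proportional"),
               setNames(c(0.5, 0.5), c(SGP, region_label("United Kingdom", "England"))))
  # direct flight: both conventions coincide
  for (m in c("last_port", "proportional")) {
    expect_equal(attribute_itinerary(c("AKL", "MEL"), 4, pm, m),
                 setNames(4.0, NZN))
  }
  expect_error(attribute_itinerary(c("XXX", "SYD"), 1, pm), "unmapped")
  expect_error(attribute_itinerary("SYD", 1, pm), "two stops")
  expect_error(attribute_itinerary(c("LHR", "SYD"), 0, pm), ">= 1")
})

test_that("record aggregation matches a brute-force summation oracle", {
  pm <- make_map()
  flights <- data.frame(
    stops = c("AKL/MEL", "LHR/SIN/SYD", "SIN/SYD", "POM/BNE", "LHR/SIN/SYD"),
    journeys = c(3, 2, 7, 4, 5),
    seats = c(200, 300, 250, 120, 300),
    mode = c("passenger", "passenger", "cargo", "passenger", "cargo"),
    year_month = c("2012-01", "2012-03", "2012-07", "2011-05", "2012-10"),
    stringsAsFactors = FALSE)
  ships <- data.frame(last_port = c("SIN", "AKL", "SIN"),
                      count = c(10, 2, 1),
                      year = c(2012, 2012, 2010), stringsAsFactors = FALSE)

  # single-region sanity: direct flights + a ship from the same region
  p <- aggregate_records(flights[1, ], ships[2, , drop = FALSE], pm, 2012)
  expect_equal(p$passenger_flights[p$region == NZN], 3)
  expect_equal(p$ships[p$region == NZN], 2)

  for (mode in c("last_port", "proportional")) {
    got <- aggregate_records(flights, ships, pm, 2012, mode)
    want <- oracle_aggregate(flights, ships, pm, 2012, mode)
    expect_equal(got$region, rownames(want))
    mode_cols <- c("passenger_flights", "cargo_flights", "ships")
    expect_equal(as.matrix(as.data.frame(got)[mode_cols]), want,
                 ignore_attr = TRUE)
    # conservation: attributed weight equals journeys in 2012 records
    expect_equal(sum(got$passenger_flights) + sum(got$cargo_flights),
                 sum(flights$journeys[substr(flights$year_month, 1, 4) == "2012"]))
    # order independence
    shuf <- aggregate_records(flights[c(4, 2, 5, 1, 3), ],
                              ships[c(3, 1, 2), ], pm, 2012, mode)
    expect_equal(shuf, got)
  }

  # proportional split of the two-leg itinerary, pre-rounding
  prop <- aggregate_records(flights[2, ], ships[0, ], pm, 2012, "proportional")
  expect_equal(prop$passenger_flights[prop$region == SGP], 1)
  expect_equal(prop$passenger_flights[
    prop$region == region_label("United Kingdom", "England")], 1)

  expect_error(
    aggregate_records(data.frame(stops = "ZZZ/SYD", journeys = 1, seats = 1,
                                 mode = "passenger", year_month = "2012-01",
                                 stringsAsFactors = FALSE),
                      ships[0, ], pm, 2012),
    "unmapped")
})

test_that("voyage files round-trip through their readers and writers", {
  flights <- data.frame(stops = c("AKL/MEL", "LHR/SIN/SYD"),
                        journeys = c(3, 2), seats = c(200, 300),
                        mode = c("passenger", "cargo"),
                        year_month = c("2012-01", "2012-03"),
                        stringsAsFactors = FALSE)
  ships <- data.frame(last_port = "SIN", count = 10, year = 2012,
                      stringsAsFactors = FALSE)
  pm <- make_map()
  ff <- withr::local_tempfile(fileext = ".psv")
  fs <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_flights(flights, ff)
  write_ships(ships, fs)
  write_port_map(pm, fp)
  fl2 <- read_flights(ff)
  expect_equal(fl2$stops, flights$stops)
  expect_equal(fl2$journeys, flights$journeys)
  expect_equal(fl2$seats, c(200, 0))  # cargo seats coerced to 0
  expect_equal(read_ships(fs)$count, 10)
  pm2 <- read_port_map(fp)
  expect_equal(sort(unclass(pm2)), sort(unclass(pm)))
})
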