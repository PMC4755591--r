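test_that("weighted cumulative impact matches printed worked examples", {
  expect_equal(compute_impact(c(15546, 426, 537), weight_vector(1, 1, 1)),
               16509)
  expect_equal(compute_impact(c(10812, 251, 1410), weight_vector(1, 20, 50)),
               86332)
  expect_equal(compute_impact(c(0, 0, 737), weight_vector(1, 20, 50)),
               36850)
  expect_equal(compute_impact(c(123, 45, 6), weight_vector(0, 0, 0)), 0)
  expect_error(weight_vector(-1, 0, 0), "non-negative")
  expect_error(compute_impact(c(-1, 0, 0), weight_vector(1, 1, 1)))
})

test_that("impact tables equal the per-region scalar computation", {
  set.seed(101)
  panel <- rand_panel(40)
  w <- weight_vector(1.3, 7, 0.2)
  it <- impact_table(panel, 2012, w)
  slice <- as.data.frame(panel)
  byhand <- vapply(it$region, function(r) {
    row <- slice[slice$region == r, ]
    compute_impact(c(row$passenger_flights, row$cargo_flights, row$ships), w)
  }, 0)
  expect_equal(it$impact, unname(byhand))

  one <- rand_panel(1)
  it1 <- impact_table(one, 2012, w)
  expect_equal(nrow(it1), 1L)
  expect_equal(it1$impact,
               compute_impact(as.data.frame(one)[
                 c("passenger_flights", "cargo_flights", "ships")], w))
  expect_error(impact_table(panel, 1887, w), "not present")
})

test_that("ranking is by descending impact with deterministic label ties", {
  rt <- rank_regions(impact_table(table2_panel(), 2012, weight_vector(1, 20, 50)))
  expect_equal(rt$region[1:3], c(SGP, NZN, SHANDONG))
  expect_equal(rt$rank, 1:10)

  tied <- traffic_panel(data.frame(
    region = c("Zeta", "Alpha", "Mid"), year = 2000,
    passenger_flights = c(5, 5, 7), cargo_flights = 0, ships = 0))
  rt2 <- rank_regions(impact_table(tied, 2000, weight_vector(1, 1, 1)))
  expect_equal(rt2$region, c("Mid", "Alpha", "Zeta"))  # tie: label order

  expect_error(rank_regions(impact_table(tied, 2000, weight_vector(0, 0, 0))),
               "all-zero")
  empty <- impact_table(tied, 2000, weight_vector(1, 1, 1))[0, ]
  class(empty) <- c("impact_table", "data.frame")
  expect_error(rank_regions(empty), "empty")
})

test_that("rankings depend only on weight ratios and collapse per mode", {
  set.seed(77)
  for (i in 1:20) {
    panel <- rand_panel(25)
    w <- weight_vector(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5) + 0.1)
    alpha <- runif(1, 0.1, 40)
    r1 <- rank_regions(impact_table(panel, 2012, w))
    r2 <- rank_regions(impact_table(panel, 2012,
                                    weight_vector(alpha * w[["wp"]],
                                                  alpha * w[["wc"]],
                                                  alpha * w[["ws"]])))
    expect_equal(r1$region, r2$region)
    # linearity of the score itself
    expect_equal(r2$impact, alpha * r1$impact)
  }
  # unit-vector weights reduce to single-mode orderings
  panel <- rand_panel(30)
  slice <- as.data.frame(panel)
  r_p <- rank_regions(impact_table(panel, 2012, weight_vector(1, 0, 0)))
  expect_equal(r_p$region,
               slice$region[order(-slice$passenger_flights, slice$region,
                                  method = "radix")])
  r_s <- rank_regions(impact_table(panel, 2012, weight_vector(0, 0, 1)))
  expect_equal(r_s$region,
               slice$region[order(-slice$ships, slice$region,
                                  method = "radix")])
  # additivity: panel total equals impact of the summed counts
  w <- weight_vector(2, 3, 4)
  expect_equal(sum(impact_table(panel, 2012, w)$impact),
               compute_impact(c(sum(slice$passenger_flights),
                                sum(slice$cargo_flights),
                                sum(slice$ships)), w))
})

test_that("total-impact percent change between years is exact", {
  p <- traffic_panel(data.frame(
    region = rep(c("A", "B"), 2), year = rep(c(1999, 2012), each = 2),
    passenger_flights = c(60, 40, 120, 73),
    cargo_flights = 0, ships = 0))
  w <- weight_vector(1, 0, 0)
  expect_equal(impact_change_pct(p, w, 1999, 2012), 93)  # 100 -> 193
  expect_equal(impact_change_pct(p, w, 1999, 1999), 0)

  set.seed(5)
  p2 <- traffic_panel(do.call(rbind, lapply(c(1999, 2012), function(y) {
    data.frame(region = sprintf("R%02d", 1:12), year = y,
               passenger_flights = rpois(12, 20),
               cargo_flights = rpois(12, 5), ships = rpois(12, 8))
  })))
  w2 <- weight_vector(1, 20, 50)
  tot <- function(y) {
    s <- as.data.frame(p2)[as.data.frame(p2)$year == y, ]
    sum(s$passenger_flights + 20 * s$cargo_flights + 50 * s$ships)
  }
  expect_equal(impact_change_pct(p2, w2, 1999, 2012),
               100 * (tot(2012) - tot(1999)) / tot(1999))

  z <- traffic_panel(data.frame(region = "A", year = c(1999, 2012),
                                passenger_flights = c(0, 5),
                                cargo_flights = 0, ships = 0))
  expect_error(impact_change_pct(z, w, 1999, 2012), "zero total")
})

test_that("rank trajectories track per-year rankings and omit absent years", {
  # a shipping surge region climbs under ship-heavy weights
  years <- c(1999, 2012)
  surge <- traffic_panel(rbind(
    data.frame(region = "Surgestan", year = years,
               passenger_flights = 0, cargo_flights = 0,
               ships = c(27, 737)),
    do.call(rbind, lapply(years, function(y) {
      data.frame(region = sprintf("Static%02d", 1:9), year = y,
                 passenger_flights = 50 * (1:9), cargo_flights = 10,
                 ships = 100)
    }))))
  w_ship <- weight_vector(1, 1, 50)
  traj <- rank_trajectory(surge, w_ship, "Surgestan")
  expect_equal(names(traj), c("1999", "2012"))
  expect_lt(traj[["2012"]], traj[["1999"]])
  # brute-force cross-check of each year against rank_regions
  for (y in years) {
    rt <- rank_regions(impact_table(surge, y, w_ship))
    expect_equal(traj[[as.character(y)]], rt$rank[rt$region == "Surgestan"])
  }

  gap <- traffic_panel(data.frame(
    region = c("A", "B", "A", "A", "B"),
    year = c(2000, 2000, 2001, 2002, 2002),
    passenger_flights = c(5, 9, 5, 5, 2), cargo_flights = 0, ships = 0))
  tb <- rank_trajectory(gap, weight_vector(1, 1, 1), "B")
  expect_equal(names(tb), c("2000", "2002"))  # 2001 omitted
  expect_equal(unname(tb), c(1L, 2L))
  expect_error(rank_trajectory(gap, weight_vector(1, 1, 1), "Nowhere"),
               "not present")
})

test_that("impact and rank tables export as csv and json", {
  it <- impact_table(table1_panel(), 2012, weight_vector(1, 1, 1))
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_table(it, fc, "csv")
  df <- read.csv(fc, fileEncoding = "UTF-8", check.names = FALSE)
  expect_equal(names(df), c("region", "I", "rank"))
  expect_equal(df$I[df$rank == 1], 16509)
  write_table(rank_regions(it), fj, "json")
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$region[js$rank == 2], SGP)
})
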