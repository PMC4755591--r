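# Shared fixtures and independent oracles.

fixture_panel <- function(name) {
  read_panel(system.file("extdata", name, package = "transportrisk"))
}

table1_panel <- function() fixture_panel("table1_2012.csv")
table2_panel <- function() fixture_panel("table2_2012.csv")
union_panel <- function() fixture_panel("tables12_union_2012.csv")
table4_panel <- function() fixture_panel("table4_2012.csv")

NZN <- "New Zealand—North Island"
NZS <- "New Zealand—South Island"
SGP <- "Singapore"
HKG <- "Hong Kong"
BALI <- "Indonesia—Bali"
SHANDONG <- "China—Shandong"
JIANGSU <- "China—Jiangsu"
TAIWAN <- "Taiwan (Province of China)"

# Random integer panel with zeros and occasional ties (Poisson counts,
# a fraction of cells zeroed), for property-style tests.
rand_panel <- function(n, year = 2012, lambda = c(30, 8, 12),
                       zero_prob = 0.3) {
  counts <- vapply(seq_len(3L), function(j) {
    stats::rpois(n, lambda[j]) * stats::rbinom(n, 1L, 1 - zero_prob)
  }, numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L)
  traffic_panel(data.frame(
    region = region_label("Testland", sprintf("R%03d", seq_len(n))),
    year = year,
    passenger_flights = counts[, 1L],
    cargo_flights = counts[, 2L],
    ships = counts[, 3L],
    stringsAsFactors = FALSE))
}

# Oracle: per-region sums of voyage records by plain accumulation over
# expanded rows (independent of aggregate_records internals).
oracle_aggregate <- function(flights, ships, map, year, mode) {
  lab <- unclass(map)
  acc <- list()
  bump <- function(region, col, w) {
    if (is.null(acc[[region]])) {
      acc[[region]] <<- c(passenger_flights = 0, cargo_flights = 0, ships = 0)
    }
    acc[[region]][col] <<- acc[[region]][col] + w
  }
  for (i in seq_len(nrow(flights))) {
    if (as.integer(substr(flights$year_month[i], 1, 4)) != year) next
    stops <- strsplit(flights$stops[i], "/", fixed = TRUE)[[1L]]
    origins <- stops[-length(stops)]
    col <- if (flights$mode[i] == "cargo") "cargo_flights" else "passenger_flights"
    if (mode == "last_port") {
      bump(lab[[origins[length(origins)]]], col, flights$journeys[i])
    } else {
      for (s in origins) {
        bump(lab[[s]], col, flights$journeys[i] / length(origins))
      }
    }
  }
  for (i in seq_len(nrow(ships))) {
    if (ships$year[i] != year) next
    bump(lab[[ships$last_port[i]]], "ships", ships$count[i])
  }
  out <- do.call(rbind, acc)
  out <- out[order(enc2utf8(rownames(out)), method = "radix"), , drop = FALSE]
  out
}

# Oracle: grid scan for the smallest focal weight (others at 1) whose
# combined score order is a linear extension of the focal-mode weak
# order. Monotone in w, so the first consistent grid point suffices.
oracle_infimum <- function(panel, year, mode, upper, step = 0.01) {
  slice <- as.data.frame(panel[panel$year == year, ])
  focal <- switch(mode, passenger = "passenger_flights",
                  cargo = "cargo_flights", ship = "ships")
  m <- slice[[focal]]
  f <- rowSums(slice[setdiff(c("passenger_flights", "cargo_flights", "ships"),
                             focal)])
  consistent <- function(w) {
    impact <- f + w * m
    dm <- outer(m, m, "-")
    di <- outer(impact, impact, "-")
    !any(dm > 0 & di <= 0)
  }
  for (w in seq(1, upper, by = step)) {
    if (consistent(w)) return(w)
  }
  NA_real_
}

# Cell-by-cell top-k sets computed through the plain ranking path,
# as an oracle for the vectorised phase diagram.
oracle_topk_grid <- function(panel, year, w_p, wc_seq, ws_seq, k) {
  out <- list()
  for (ws in ws_seq) {
    for (wc in wc_seq) {
      out[[length(out) + 1L]] <-
        sort(top_k_set(panel, year, weight_vector(w_p, wc, ws), k))
    }
  }
  out
}

# Phase sets of a diagram in cell order (wc fastest, ws ascending).
diagram_cell_sets <- function(d) {
  lapply(d$cells$phase, function(lbl) sort(d$phases[[lbl]]))
}
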