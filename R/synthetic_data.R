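## synthetic_data: traffic-panel and voyage-record generator.

#' Configuration for the synthetic traffic generator
#'
#' Describes a panel of source regions with the statistical structure of
#' real multi-pathway traffic into an island nation: heavy-tailed
#' (log-normal) per-mode volumes; a small set of hub regions with
#' correlated high volumes across all three modes (global transport
#' hubs); many single-mode regions (two modes exactly zero — e.g.
#' passenger-only holiday destinations, ship-only bulk-cargo provinces);
#' per-region multiplicative annual growth; and a few "surge" regions
#' whose shipping grows by an order of magnitude over the period (the
#' empirical pattern of some Chinese provinces, roughly 27-fold over 14
#' years).
#'
#' Default magnitudes are calibrated so that a ~300-region, 14-year
#' panel carries on the order of 70,000 flights and 10,000 ship arrivals
#' per year — the scale of national inbound traffic data.
#'
#' @param n_regions Number of source regions.
#' @param years Integer vector of consecutive calendar years.
#' @param hub_fraction Fraction of regions that are all-mode hubs.
#' @param single_mode_fraction Fraction of regions with traffic in
#'   exactly one mode (cycled over the three modes).
#' @param volume_meanlog,volume_sdlog Per-mode log-normal parameters for
#'   baseline annual volumes, named `passenger`, `cargo`, `ships`.
#' @param hub_shift Added to `meanlog` for hub regions (log scale).
#' @param mode_cor Correlation of per-mode log-volumes induced by a
#'   shared per-region size factor, in `[0, 1]`.
#' @param growth_mean,growth_sd Mean and s.d. of the per-region annual
#'   multiplicative growth rate per mode (named as above).
#' @param surge_fraction Fraction of ship-traffic regions given a surge
#'   trajectory.
#' @param surge_ratio Target ratio of last-year to first-year ship
#'   counts for surge regions.
#' @param surge_sdlog Log-scale spread of the realised surge ratios.
#' @param multi_stop_fraction Fraction of passenger/cargo flights given
#'   a two-leg itinerary by [generate_itineraries()].
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 300,
                             years = 1999:2012,
                             hub_fraction = 0.05,
                             single_mode_fraction = 0.55,
                             volume_meanlog = c(passenger = 4.0,
                                                cargo = 1.8,
                                                ships = 2.5),
                             volume_sdlog = c(passenger = 1.6,
                                              cargo = 1.3,
                                              ships = 1.4),
                             hub_shift = 2.5,
                             mode_cor = 0.7,
                             growth_mean = c(passenger = 1.05,
                                             cargo = 1.04,
                                             ships = 1.03),
                             growth_sd = 0.04,
                             surge_fraction = 0.02,
                             surge_ratio = 27,
                             surge_sdlog = 0.25,
                             multi_stop_fraction = 0.3,
                             seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              years = as.integer(years),
              hub_fraction = hub_fraction,
              single_mode_fraction = single_mode_fraction,
              volume_meanlog = volume_meanlog,
              volume_sdlog = volume_sdlog,
              hub_shift = hub_shift,
              mode_cor = mode_cor,
              growth_mean = growth_mean,
              growth_sd = growth_sd,
              surge_fraction = surge_fraction,
              surge_ratio = surge_ratio,
              surge_sdlog = surge_sdlog,
              multi_stop_fraction = multi_stop_fraction,
              seed = as.integer(seed))
  if (cfg$n_regions < 1L) stop("n_regions must be >= 1", call. = FALSE)
  if (length(cfg$years) < 1L) stop("years must be non-empty", call. = FALSE)
  fr <- c(cfg$hub_fraction, cfg$single_mode_fraction, cfg$surge_fraction,
          cfg$multi_stop_fraction)
  if (any(fr < 0) || any(fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$hub_fraction + cfg$single_mode_fraction > 1) {
    stop("hub_fraction + single_mode_fraction must be <= 1", call. = FALSE)
  }
  if (cfg$mode_cor < 0 || cfg$mode_cor > 1) {
    stop("mode_cor must lie in [0, 1]", call. = FALSE)
  }
  mode_names <- c("passenger", "cargo", "ships")
  for (p in c("volume_meanlog", "volume_sdlog", "growth_mean")) {
    if (!all(mode_names %in% names(cfg[[p]]))) {
      stop(p, " must be named passenger, cargo, ships", call. = FALSE)
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_region_labels <- function(n) {
  region_label("Simuland", sprintf("R%03d", seq_len(n)))
}

synthetic_port_codes <- function(n) sprintf("PT%03d", seq_len(n))

#' Generate a synthetic traffic panel
#'
#' Draws a region-by-year panel under a [synthetic_config()]. Each
#' region gets a latent size factor shared across modes (inducing the
#' hub-like cross-mode correlation), a per-mode baseline volume drawn
#' log-normally (hub regions from an upshifted distribution), and a
#' per-mode annual growth rate; single-mode regions keep exactly one
#' mode, and surge regions follow a shipping trajectory whose
#' last/first-year ratio is log-normally spread around
#' `surge_ratio`. Counts are integerised half-up; identical config and
#' seed give identical panels.
#'
#' @param cfg A [synthetic_config()].
#' @return A [traffic_panel()] covering all `cfg$years`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_regions
  years <- cfg$years
  ny <- length(years)
  modes <- c("passenger", "cargo", "ships")
  mode_col <- c(passenger = "passenger_flights", cargo = "cargo_flights",
                ships = "ships")

  n_hub <- round_half_up(cfg$hub_fraction * n)
  n_single <- round_half_up(cfg$single_mode_fraction * n)
  if (n_hub + n_single > n) n_single <- n - n_hub
  type <- rep("mixed", n)
  if (n_hub > 0L) type[seq_len(n_hub)] <- "hub"
  if (n_single > 0L) type[n_hub + seq_len(n_single)] <- "single"
  single_mode <- rep(modes, length.out = max(n_single, 1L))

  z <- rnorm(n)  # shared size factor
  base <- matrix(0, nrow = n, ncol = 3L, dimnames = list(NULL, modes))
  for (j in seq_along(modes)) {
    m <- modes[j]
    eps <- rnorm(n)
    x <- cfg$mode_cor * z + sqrt(1 - cfg$mode_cor^2) * eps
    mu <- cfg$volume_meanlog[[m]] + ifelse(type == "hub", cfg$hub_shift, 0)
    base[, j] <- exp(mu + cfg$volume_sdlog[[m]] * x)
  }
  single_idx <- which(type == "single")
  if (length(single_idx)) {
    kept <- single_mode[seq_along(single_idx)]  # the one mode each keeps
    for (j in seq_along(modes)) {
      base[single_idx[kept != modes[j]], j] <- 0
    }
  }

  growth <- matrix(0, nrow = n, ncol = 3L, dimnames = list(NULL, modes))
  for (j in seq_along(modes)) {
    growth[, j] <- pmax(0.5, rnorm(n, cfg$growth_mean[[modes[j]]],
                                   cfg$growth_sd))
  }

  ## surge regions: among regions with ship traffic, pin the shipping
  ## growth so the full-period ratio lands near surge_ratio
  has_ships <- base[, "ships"] > 0
  n_surge <- round_half_up(cfg$surge_fraction * n)
  surge_idx <- integer(0)
  if (n_surge > 0L && any(has_ships) && ny > 1L) {
    pool <- which(has_ships)
    surge_idx <- pool[seq_len(min(n_surge, length(pool)))]
    ratios <- cfg$surge_ratio * exp(rnorm(length(surge_idx), 0, cfg$surge_sdlog))
    growth[surge_idx, "ships"] <- ratios^(1 / (ny - 1))
    ## keep first-year ship counts in a modest band so the integerised
    ## trajectory preserves the ratio
    base[surge_idx, "ships"] <- pmax(base[surge_idx, "ships"], 20)
  }

  rows <- vector("list", ny)
  labels <- synthetic_region_labels(n)
  for (t in seq_len(ny)) {
    counts <- base * growth^(t - 1L)
    rows[[t]] <- data.frame(region = labels, year = years[t],
                            passenger_flights = round_half_up(counts[, "passenger"]),
                            cargo_flights = round_half_up(counts[, "cargo"]),
                            ships = round_half_up(counts[, "ships"]),
                            stringsAsFactors = FALSE)
  }
  panel <- traffic_panel(do.call(rbind, rows))
  attr(panel, "surge_regions") <- labels[surge_idx]
  panel
}

#' Generate voyage-level records consistent with a panel
#'
#' Produces flight itineraries, ship arrivals and a port map whose
#' last-port aggregation reproduces the panel exactly (one port per
#' region). A configurable fraction of flights get a two-leg itinerary
#' with an upstream foreign stop (the next region, cyclically), so
#' last-port and proportional attribution differ; with
#' `multi_stop_fraction = 0` the two conventions coincide.
#'
#' @param cfg A [synthetic_config()].
#' @param panel A panel from [generate_panel()] (or any integer-valued
#'   [traffic_panel()] whose regions are the synthetic labels).
#' @return A list with elements `flights`, `ships` (data.frames in the
#'   voyage-file layouts) and `map` (a [port_region_map()]).
#' @export
generate_itineraries <- function(cfg, panel) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(panel, "traffic_panel"))
  regions <- panel_regions(panel)
  n <- length(regions)
  ports <- setNames(synthetic_port_codes(n), regions)
  upstream <- if (n > 1L) ports[c(2:n, 1L)] else ports  # next region, cyclic
  names(upstream) <- regions
  ms <- if (n > 1L) cfg$multi_stop_fraction else 0

  fl <- list()
  sh <- list()
  for (i in seq_len(nrow(panel))) {
    reg <- panel$region[i]
    yr <- panel$year[i]
    ym <- sprintf("%d-06", yr)
    for (fm in c("passenger", "cargo")) {
      ct <- panel[[if (fm == "passenger") "passenger_flights" else "cargo_flights"]][i]
      if (ct <= 0) next
      n_multi <- round_half_up(ms * ct)
      n_direct <- ct - n_multi
      seats <- if (fm == "passenger") 180 else 0
      if (n_direct > 0) {
        fl[[length(fl) + 1L]] <- data.frame(
          stops = paste(ports[[reg]], "AUS", sep = "/"),
          journeys = n_direct, seats = seats, mode = fm, year_month = ym,
          stringsAsFactors = FALSE)
      }
      if (n_multi > 0) {
        fl[[length(fl) + 1L]] <- data.frame(
          stops = paste(upstream[[reg]], ports[[reg]], "AUS", sep = "/"),
          journeys = n_multi, seats = seats, mode = fm, year_month = ym,
          stringsAsFactors = FALSE)
      }
    }
    if (panel$ships[i] > 0) {
      sh[[length(sh) + 1L]] <- data.frame(last_port = ports[[reg]],
                                          count = panel$ships[i], year = yr,
                                          stringsAsFactors = FALSE)
    }
  }
  flights <- if (length(fl)) do.call(rbind, fl) else {
    data.frame(stops = character(), journeys = numeric(), seats = numeric(),
               mode = character(), year_month = character(),
               stringsAsFactors = FALSE)
  }
  flights$year <- as.integer(substr(flights$year_month, 1L, 4L))
  ships <- if (length(sh)) do.call(rbind, sh) else {
    data.frame(last_port = character(), count = numeric(), year = integer(),
               stringsAsFactors = FALSE)
  }
  parts <- split_region_label(regions)
  map <- port_region_map(data.frame(port = unname(ports),
                                    country = parts$country,
                                    subdivision = parts$subdivision,
                                    stringsAsFactors = FALSE))
  list(flights = flights, ships = ships, map = map)
}
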