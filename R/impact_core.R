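## impact_core: weighted cumulative impact, rankings and temporal change.

#' Pathway weight vector
#'
#' The three non-negative pathway risk weights: `wp` for passenger
#' flights, `wc` for cargo flights and `ws` for ship arrivals. The
#' weights encode how much more or less likely one transport type is to
#' carry a threat than another; only their ratios matter for rankings
#' (impact is linear, so rankings are invariant under positive scaling).
#' An all-zero vector is a valid argument for impact computation (every
#' score is 0) but is rejected by ranking functions.
#'
#' @param wp,wc,ws Non-negative finite reals.
#' @return A named numeric vector of class `weight_vector`.
#' @examples
#' weight_vector(1, 20, 50)
#' @export
weight_vector <- function(wp = 1, wc = 1, ws = 1) {
  w <- c(wp = as.numeric(wp), wc = as.numeric(wc), ws = as.numeric(ws))
  if (anyNA(w) || any(w < 0) || any(!is.finite(w))) {
    stop("weights must be non-negative finite reals", call. = FALSE)
  }
  class(w) <- "weight_vector"
  w
}

as_weight_vector <- function(w) {
  if (inherits(w, "weight_vector")) return(w)
  if (is.numeric(w) && length(w) == 3L) {
    return(weight_vector(w[[1L]], w[[2L]], w[[3L]]))
  }
  stop("w must be a weight_vector or numeric vector of length 3", call. = FALSE)
}

#' Weighted cumulative impact of a set of mode counts
#'
#' The core risk score: `I = wp * passenger_flights + wc * cargo_flights
#' + ws * ships`. With Table-style 2012 counts for Singapore
#' (10812, 251, 1410) and weights (1, 20, 50) this gives 86332.
#'
#' @param counts A numeric vector `c(passenger_flights, cargo_flights,
#'   ships)`, or a data.frame with those columns (one score per row).
#' @param w A [weight_vector()] or numeric length-3 vector.
#' @return Numeric impact score(s).
#' @examples
#' compute_impact(c(10812, 251, 1410), weight_vector(1, 20, 50))
#' @export
compute_impact <- function(counts, w) {
  w <- as_weight_vector(w)
  if (is.data.frame(counts)) {
    stopifnot(all(MODE_COLS %in% names(counts)))
    m <- as.matrix(counts[MODE_COLS])
  } else {
    counts <- as.numeric(counts)
    if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
      stop("counts must be three non-negative numbers", call. = FALSE)
    }
    m <- matrix(counts, nrow = 1L)
  }
  drop(m %*% unclass(w))
}

#' Impact table for one panel year
#'
#' Applies the weighted cumulative impact score to every region present
#' in the panel for the given year. Regions with no entry in that year
#' are excluded (absent entries read as zero traffic only when the
#' region is explicitly present); regions explicitly present with
#' all-zero counts are retained, which keeps ranking denominators stable
#' across weightings.
#'
#' @param panel A [traffic_panel()].
#' @param year A year present in the panel.
#' @param w A [weight_vector()].
#' @return A data.frame of class `impact_table` with columns `region`,
#'   `passenger_flights`, `cargo_flights`, `ships`, `impact`, carrying
#'   `year` and `weights` attributes.
#' @export
impact_table <- function(panel, year, w) {
  w <- as_weight_vector(w)
  slice <- panel_slice(panel, year)
  out <- data.frame(region = slice$region,
                    slice[MODE_COLS],
                    impact = compute_impact(slice, w),
                    stringsAsFactors = FALSE)
  out <- out[order_regions(out$region), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, year = as.integer(year), weights = w,
            class = c("impact_table", "data.frame"))
}

#' Rank regions by weighted cumulative impact
#'
#' Rank 1 is the highest-impact region. Ties (rare with real traffic
#' volumes) are broken by ascending canonical region label, giving a
#' deterministic total order — required for reproducible phase diagrams
#' and aggregate rankings.
#'
#' @param x An [impact_table()].
#' @return A data.frame of class `rank_table` with columns `region`,
#'   `impact`, `rank`, sorted by rank; `year` and `weights` attributes
#'   carried over.
#' @export
rank_regions <- function(x) {
  stopifnot(inherits(x, "impact_table"))
  if (nrow(x) == 0L) stop("cannot rank an empty impact table", call. = FALSE)
  w <- attr(x, "weights")
  if (!is.null(w) && all(unclass(w) == 0)) {
    stop("cannot rank with an all-zero weight vector", call. = FALSE)
  }
  ord <- order(-x$impact, x$region, method = "radix")
  out <- data.frame(region = x$region[ord], impact = x$impact[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(out, year = attr(x, "year"), weights = w,
            class = c("rank_table", "data.frame"))
}

#' Percent change in total weighted cumulative impact between two years
#'
#' Sums impact over all regions in each year and reports
#' `100 * (total_b - total_a) / total_a`. With passenger-only weights
#' this is the kind of quantity behind statements like "passenger-flight
#' impact grew 93% over the study period".
#'
#' @param panel A [traffic_panel()].
#' @param w A [weight_vector()].
#' @param year_a,year_b Baseline and comparison years (both present).
#' @return Percent change (real, unrounded).
#' @export
impact_change_pct <- function(panel, w, year_a, year_b) {
  w <- as_weight_vector(w)
  total_a <- sum(compute_impact(panel_slice(panel, year_a), w))
  total_b <- sum(compute_impact(panel_slice(panel, year_b), w))
  if (total_a == 0) {
    stop("baseline year has zero total impact; percent change undefined",
         call. = FALSE)
  }
  100 * (total_b - total_a) / total_a
}

#' Rank trajectory of one region over time
#'
#' Recomputes the full ranking for every panel year and extracts the
#' focal region's rank; years in which the region has no panel entry are
#' omitted. This is the "1999 rank" style column of ranked-impact
#' tables: e.g. a region whose shipping grows 27-fold while others are
#' static climbs steeply under ship-heavy weights.
#'
#' @param panel A [traffic_panel()].
#' @param w A [weight_vector()].
#' @param region Canonical region label present in at least one year.
#' @return Named integer vector, year -> rank.
#' @export
rank_trajectory <- function(panel, w, region) {
  w <- as_weight_vector(w)
  if (!region %in% panel$region) {
    stop(sprintf("region '%s' not present in panel", region), call. = FALSE)
  }
  years <- panel_years(panel)
  out <- integer(0)
  for (y in years) {
    slice <- panel[panel$year == y, , drop = FALSE]
    if (!region %in% slice$region) next
    rt <- rank_regions(impact_table(panel, y, w))
    out[as.character(y)] <- rt$rank[rt$region == region]
  }
  out
}

#' Export an impact or rank table as delimited text
#'
#' Writes `region,I,rank` (plus mode counts for impact tables) as CSV,
#' or the same fields as JSON.
#'
#' @param x An [impact_table()] or [rank_regions()] result.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (inherits(x, "impact_table")) {
    ord <- order(-df$impact, df$region, method = "radix")
    df <- data.frame(region = df$region, I = df$impact,
                     rank = NA_integer_, stringsAsFactors = FALSE)
    df$rank[ord] <- seq_along(ord)
  } else if (inherits(x, "rank_table")) {
    df <- data.frame(region = df$region, I = df$impact, rank = df$rank,
                     stringsAsFactors = FALSE)
  }
  if (format == "csv") {
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
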