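## hotspot_ranking: per-mode weight bounds, weight-space sampling and
## rank aggregation.

#' Per-mode upper weight bounds
#'
#' Upper limits of the weight ranges explored by the overall hotspot
#' ranking; the lower bound of every range is 1. Bounds are typically
#' produced by [compute_bounds()] (the infimum search), but can be
#' supplied directly, e.g. bounds derived from another panel.
#'
#' @param bp,bc,bs Upper bounds (>= 1) for the passenger, cargo and ship
#'   weights.
#' @return Named numeric vector of class `parameter_bounds`.
#' @export
parameter_bounds <- function(bp, bc, bs) {
  b <- c(bp = as.numeric(bp), bc = as.numeric(bc), bs = as.numeric(bs))
  if (anyNA(b) || any(b < 1) || any(!is.finite(b))) {
    stop("each bound must be a finite real >= 1", call. = FALSE)
  }
  class(b) <- "parameter_bounds"
  b
}

#' Infimum weight at which one mode dictates the ranking
#'
#' With the other two weights fixed at 1, finds the smallest focal-mode
#' weight beyond which the combined ranking agrees with the ranking by
#' that mode alone — the infimum of the set of consistent weights, used
#' as the upper bound of the explored range for that mode. Agreement is
#' with the focal-mode *weak* order: the combined ranking must be a
#' linear extension of it, so region pairs tied on the focal mode (very
#' common, e.g. both zero) place no constraint; with a strict-order
#' reading the infimum would be infinite whenever ties exist.
#'
#' Closed form: writing `m` for focal-mode counts and `f` for the sum of
#' the other two modes' counts, a pair with `m_a > m_b` is ordered
#' consistently for every `w > (f_b - f_a) / (m_a - m_b)`; the infimum
#' is the largest such pairwise threshold, floored at 1 (the lower end
#' of the explored range). If all regions are tied on the focal mode the
#' result is 1 (any weight is consistent).
#'
#' @param panel A [traffic_panel()].
#' @param year Year to analyse (>= 2 regions present).
#' @param mode `"passenger"`, `"cargo"` or `"ship"`.
#' @return The infimum weight (real >= 1).
#' @export
infimum_weight <- function(panel, year, mode = c("passenger", "cargo", "ship")) {
  mode <- match.arg(mode)
  slice <- panel_slice(panel, year)
  if (nrow(slice) < 2L) {
    stop("infimum search needs at least two regions", call. = FALSE)
  }
  focal_col <- switch(mode, passenger = "passenger_flights",
                      cargo = "cargo_flights", ship = "ships")
  m <- slice[[focal_col]]
  f <- rowSums(slice[setdiff(MODE_COLS, focal_col)])
  dm <- outer(m, m, "-")   # dm[a, b] = m_a - m_b
  df <- outer(f, f, "-")
  pos <- dm > 0
  if (!any(pos)) return(1)
  max(1, max(-df[pos] / dm[pos]))
}

#' Bounds for all three modes
#'
#' Runs [infimum_weight()] for each mode and packages the results as
#' [parameter_bounds()].
#'
#' @inheritParams infimum_weight
#' @return A [parameter_bounds()].
#' @export
compute_bounds <- function(panel, year) {
  parameter_bounds(infimum_weight(panel, year, "passenger"),
                   infimum_weight(panel, year, "cargo"),
                   infimum_weight(panel, year, "ship"))
}

#' Sample pathway weightings over the bounded weight space
#'
#' Draws `n_per_face` weight vectors on each of the three faces of the
#' weight space: one coordinate fixed at 1 (so every sampled ratio trio
#' is interpretable directly) and the other two independent uniform on
#' `[1, bound]`. With the published-style `n_per_face = 10000` this
#' gives 30,000 points. Continuous draws make duplicate ratio trios a
#' probability-zero event; a `collisions` attribute reports any exact
#' duplicates observed (relevant only for degenerate bounds).
#'
#' @param bounds A [parameter_bounds()].
#' @param n_per_face Draws per face (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame of class `weight_sample` with columns `wp`,
#'   `wc`, `ws` and a `face` column recording which weight was fixed;
#'   attributes `bounds`, `n_per_face`, `seed`, `collisions`.
#' @export
sample_weightings <- function(bounds, n_per_face = 10000, seed = NULL) {
  stopifnot(inherits(bounds, "parameter_bounds"), n_per_face >= 1)
  n_per_face <- as.integer(n_per_face)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(b, n) runif(n, min = 1, max = b)
  faces <- list(
    p = data.frame(wp = rep(1, n_per_face),
                   wc = draw(bounds[["bc"]], n_per_face),
                   ws = draw(bounds[["bs"]], n_per_face),
                   face = "p", stringsAsFactors = FALSE),
    c = data.frame(wp = draw(bounds[["bp"]], n_per_face),
                   wc = rep(1, n_per_face),
                   ws = draw(bounds[["bs"]], n_per_face),
                   face = "c", stringsAsFactors = FALSE),
    s = data.frame(wp = draw(bounds[["bp"]], n_per_face),
                   wc = draw(bounds[["bc"]], n_per_face),
                   ws = rep(1, n_per_face),
                   face = "s", stringsAsFactors = FALSE))
  out <- do.call(rbind, faces)
  rownames(out) <- NULL
  ratio_key <- paste(out$wc / out$wp, out$ws / out$wp)
  structure(out, bounds = bounds, n_per_face = n_per_face, seed = seed,
            collisions = sum(duplicated(ratio_key)),
            class = c("weight_sample", "data.frame"))
}

#' Aggregate rankings over a weight sample
#'
#' Ranks every region at every sampled weighting (deterministic
#' impact/label tie-break) and accumulates, per region: the aggregate
#' ranking value (sum of rank positions over all points — a region that
#' ranked first everywhere would score exactly the number of points),
#' and the percentage of points at which the region was in the top 1, 5,
#' 10 and 50. Regions with minimal aggregate ranking value are the
#' overall hotspots.
#'
#' @param panel A [traffic_panel()].
#' @param year Year to analyse.
#' @param sample A [sample_weightings()] result (or data.frame with
#'   `wp`, `wc`, `ws`).
#' @param top_k Integer vector of top-set sizes to report membership
#'   percentages for.
#' @return A data.frame of class `hotspot_summary`, ordered by
#'   ascending aggregate rank (ties by label), with columns `region`,
#'   `aggregate_rank`, `prop_top1`, `prop_top5`, `prop_top10`,
#'   `prop_top50` and the three mode-count columns for the year;
#'   attribute `n_points`.
#' @export
aggregate_ranking <- function(panel, year, sample,
                              top_k = c(1, 5, 10, 50)) {
  slice <- panel_slice(panel, year)
  if (nrow(sample) == 0L) stop("empty weight sample", call. = FALSE)
  ord0 <- order_regions(slice$region)
  slice <- slice[ord0, , drop = FALSE]      # label order => stable tie-break
  counts <- as.matrix(slice[MODE_COLS])
  W <- t(as.matrix(sample[c("wp", "wc", "ws")]))  # 3 x N
  S <- counts %*% W                                # R x N
  R <- nrow(S)
  N <- ncol(S)
  agg <- numeric(R)
  topn <- matrix(0, nrow = R, ncol = length(top_k))
  for (j in seq_len(N)) {
    ord <- order(-S[, j], method = "radix")  # stable: label tie-break
    r <- integer(R)
    r[ord] <- seq_len(R)
    agg <- agg + r
    for (t in seq_along(top_k)) {
      topn[, t] <- topn[, t] + (r <= top_k[t])
    }
  }
  out <- data.frame(region = slice$region, aggregate_rank = agg,
                    stringsAsFactors = FALSE)
  for (t in seq_along(top_k)) {
    out[[paste0("prop_top", top_k[t])]] <- 100 * topn[, t] / N
  }
  out <- cbind(out, slice[MODE_COLS])
  ord <- order(out$aggregate_rank, out$region, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_points = N, year = as.integer(year),
            class = c("hotspot_summary", "data.frame"))
}

#' Overall hotspot ordering
#'
#' Regions ordered by ascending aggregate ranking value (smaller =
#' higher overall risk), ties broken by canonical label.
#'
#' @param summary A [aggregate_ranking()] result.
#' @return Character vector of region labels.
#' @export
overall_ranking <- function(summary) {
  stopifnot(inherits(summary, "hotspot_summary"))
  if (nrow(summary) == 0L) stop("empty hotspot summary", call. = FALSE)
  summary$region[order(summary$aggregate_rank, summary$region,
                       method = "radix")]
}

#' Export a hotspot summary or weight sample
#'
#' The summary is written in ranked-table layout
#' (`region,aggregate_rank,prop_top1,...,ships`); the sample as
#' `wp,wc,ws`.
#'
#' @param x A `hotspot_summary` or `weight_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspot <- function(x, path) {
  if (inherits(x, "weight_sample")) {
    write.table(as.data.frame(x)[c("wp", "wc", "ws")], path, sep = ",",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    stopifnot(inherits(x, "hotspot_summary"))
    write.table(as.data.frame(x), path, sep = ",", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
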