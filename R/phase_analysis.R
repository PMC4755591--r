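## phase_analysis: top-k phase structure of the weight space.

#' Top-k regions at one weighting
#'
#' First `k` entries of the impact ranking (deterministic label
#' tie-break). If fewer than `k` regions are present, all are returned.
#'
#' @param panel A [traffic_panel()].
#' @param year Year to analyse.
#' @param w A [weight_vector()].
#' @param k Number of regions (default 5).
#' @return Character vector of region labels in rank order.
#' @export
top_k_set <- function(panel, year, w, k = 5) {
  stopifnot(k >= 1)
  rt <- rank_regions(impact_table(panel, year, w))
  head(rt$region, k)
}

#' Share of total impact held by the top-k regions
#'
#' The "top-heaviness" of a ranking: sum of impact over the `k`
#' highest-ranked regions divided by total impact over all regions.
#' Always in `[0, 1]`, and continuous in the weights wherever the top-k
#' set does not change.
#'
#' @inheritParams top_k_set
#' @return A real in `[0, 1]`.
#' @export
top5_share <- function(panel, year, w, k = 5) {
  it <- impact_table(panel, year, w)
  total <- sum(it$impact)
  if (total == 0) {
    stop("total impact is zero; top-k share undefined", call. = FALSE)
  }
  rt <- rank_regions(it)
  sum(head(rt$impact, k)) / total
}

## Number of regions guaranteed to outrank region i at EVERY weighting
## accepted for ranking (non-negative, not all zero). j qualifies when
## it weakly dominates i mode-wise (>= in all three modes, > in at
## least one) and additionally either dominates strictly in all modes
## (so scores can never tie) or sorts before i in label order (so j
## wins any score tie under the deterministic tie-break). Weak
## domination alone is not enough: on a boundary weighting that zeroes
## the modes where j leads, the two scores tie and the label tie-break
## could favour i.
count_dominators <- function(counts, labels) {
  n <- nrow(counts)
  dom <- integer(n)
  lab_rank <- integer(n)  # position in C-locale label order
  lab_rank[order_regions(labels)] <- seq_len(n)
  for (i in seq_len(n)) {
    ge <- counts[, 1L] >= counts[i, 1L] &
          counts[, 2L] >= counts[i, 2L] &
          counts[, 3L] >= counts[i, 3L]
    gt <- counts[, 1L] > counts[i, 1L] |
          counts[, 2L] > counts[i, 2L] |
          counts[, 3L] > counts[i, 3L]
    strict <- counts[, 1L] > counts[i, 1L] &
              counts[, 2L] > counts[i, 2L] &
              counts[, 3L] > counts[i, 3L]
    dom[i] <- sum(ge & gt & (strict | lab_rank < lab_rank[i]))
  }
  dom
}

#' Prune regions that can never reach the top k
#'
#' Returns the regions that could still reach the top `k` somewhere in
#' weight space. Because impact is a non-negative linear combination of
#' the three mode counts, a region mode-wise dominated by another scores
#' no higher than its dominator at every non-negative weighting; a
#' dominator is *guaranteed* to outrank the region once the scores can
#' never tie (strict domination in all modes) or, where boundary
#' weightings allow a tie, when the dominator also wins the
#' deterministic label tie-break. A region with at least `k` such
#' guaranteed dominators can never enter the top `k` anywhere in the
#' non-negative orthant, so the surviving set is a superset of every
#' attainable top-k set, for any weight box. Pruning makes dense
#' phase-diagram grids tractable without changing results.
#'
#' @param panel A [traffic_panel()].
#' @param year Year to analyse.
#' @param k Top-set size the pruning must preserve (default 5).
#' @return Character vector of retained region labels, C-locale sorted.
#' @export
candidate_prune <- function(panel, year, k = 5) {
  slice <- panel_slice(panel, year)
  counts <- as.matrix(slice[MODE_COLS])
  keep <- count_dominators(counts, slice$region) < k
  sort_regions(slice$region[keep])
}

phase_label <- function(i) {
  # A, B, ..., Z, AA, AB, ... in first-encounter order
  out <- character(length(i))
  for (j in seq_along(i)) {
    n <- i[j]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[j] <- s
  }
  out
}

#' Phase diagram of the top-k region set over (wc, ws) space
#'
#' Holds the passenger weight fixed and evaluates the top-`k` set of
#' regions at every point of a rectangular grid over cargo and ship
#' weights (endpoints inclusive). Grid cells sharing the same top-`k`
#' set — compared as a *set* by default, since the scientific question
#' is which regions make the cut, not their internal order — form a
#' phase; phases are labelled A, B, C, ... in scan order (`wc` varying
#' fastest, then `ws` ascending). Each cell also records the top-`k`
#' share of total impact. Weights lying exactly on a phase boundary are
#' resolved by the deterministic impact/label tie-break; boundaries are
#' reported between cells, not at cells (see [extract_boundaries()]).
#'
#' @param panel A [traffic_panel()].
#' @param year Year to analyse.
#' @param w_p Fixed passenger-flight weight (default 1).
#' @param wc_range,ws_range Length-2 numeric ranges for the cargo and
#'   ship weights (default `c(0, 50)`).
#' @param step Grid spacing (default 0.01, the dense published-style
#'   grid; use a coarser step for interactive work).
#' @param k Top-set size (default 5).
#' @param prune Use [candidate_prune()] to restrict the ranking to
#'   feasible top-k candidates (identical results, much faster on large
#'   panels).
#' @param ordered Compare top-k as an ordered list instead of a set.
#' @return An object of class `phase_diagram`: list with `cells` (a
#'   data.frame `wc, ws, phase, share`), `phases` (named list,
#'   label -> region set in first-encounter rank order), plus the grid
#'   specification.
#' @export
phase_diagram <- function(panel, year, w_p = 1,
                          wc_range = c(0, 50), ws_range = c(0, 50),
                          step = 0.01, k = 5, prune = TRUE,
                          ordered = FALSE) {
  stopifnot(step > 0, length(wc_range) == 2L, length(ws_range) == 2L,
            all(wc_range >= 0), all(ws_range >= 0))
  slice <- panel_slice(panel, year)
  if (nrow(slice) == 0L) stop("empty panel year", call. = FALSE)
  wc_seq <- seq(wc_range[1L], wc_range[2L], by = step)
  ws_seq <- seq(ws_range[1L], ws_range[2L], by = step)

  regions <- slice$region
  counts <- as.matrix(slice[MODE_COLS])
  if (prune) {
    keep <- count_dominators(counts, regions) < k
  } else {
    keep <- rep(TRUE, nrow(counts))
  }
  ## order candidate rows by label so that stable ordering on score
  ## implements the label tie-break
  cand <- which(keep)[order_regions(regions[keep])]
  cregions <- regions[cand]
  ccounts <- counts[cand, , drop = FALSE]
  totals <- colSums(counts)  # share denominator uses ALL regions

  kk <- min(k, length(cregions))
  phase_keys <- character(0)
  phase_sets <- list()
  cell_phase <- integer(0)
  cell_share <- numeric(0)

  for (ws in ws_seq) {  # ws outer, wc fastest: scan order of the cells
    W <- rbind(w_p, wc_seq, ws)                 # 3 x G
    S <- ccounts %*% W                          # cand x G
    tot <- drop(totals %*% W)
    shares <- numeric(length(wc_seq))
    labels_here <- integer(length(wc_seq))
    for (g in seq_along(wc_seq)) {
      ord <- order(-S[, g], method = "radix")   # stable: label tie-break
      topi <- ord[seq_len(kk)]
      top <- cregions[topi]
      key <- paste(sort(top), collapse = "\x1f")
      if (ordered) key <- paste(top, collapse = "\x1f")
      idx <- match(key, phase_keys)
      if (is.na(idx)) {
        phase_keys <- c(phase_keys, key)
        phase_sets[[length(phase_keys)]] <- top
        idx <- length(phase_keys)
      }
      labels_here[g] <- idx
      shares[g] <- if (tot[g] > 0) sum(S[topi, g]) / tot[g] else NA_real_
    }
    cell_phase <- c(cell_phase, labels_here)
    cell_share <- c(cell_share, shares)
  }

  grid <- expand.grid(wc = wc_seq, ws = ws_seq,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- data.frame(wc = grid$wc, ws = grid$ws,
                      phase = phase_label(cell_phase),
                      share = cell_share, stringsAsFactors = FALSE)
  phases <- setNames(phase_sets, phase_label(seq_along(phase_sets)))
  structure(list(cells = cells, phases = phases, w_p = w_p,
                 wc_seq = wc_seq, ws_seq = ws_seq, step = step, k = k,
                 year = as.integer(year), ordered = ordered),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "Phase diagram: w_p = %g, wc in [%g, %g], ws in [%g, %g], step %g\n",
    x$w_p, min(x$wc_seq), max(x$wc_seq), min(x$ws_seq), max(x$ws_seq),
    x$step))
  cat(sprintf("%d cells, %d phases (top-%d %s)\n", nrow(x$cells),
              length(x$phases), x$k,
              if (isTRUE(x$ordered)) "ordered lists" else "sets"))
  for (lab in names(x$phases)) {
    cat(sprintf("  %s: %s\n", lab, paste(x$phases[[lab]], collapse = ", ")))
  }
  invisible(x)
}

#' Boundaries between phases of a phase diagram
#'
#' Returns every axis-adjacent pair of grid cells whose top-k sets
#' differ, as segments suitable for plotting or reporting. A uniform
#' diagram yields an empty set.
#'
#' @param d A [phase_diagram()].
#' @return Data.frame with columns `orientation` (`"vertical"` edges
#'   separate wc-neighbours, `"horizontal"` ws-neighbours), `wc1`,
#'   `ws1`, `wc2`, `ws2` (the two cells), `phase1`, `phase2`.
#' @export
extract_boundaries <- function(d) {
  stopifnot(inherits(d, "phase_diagram"))
  nc <- length(d$wc_seq)
  ns <- length(d$ws_seq)
  ph <- matrix(d$cells$phase, nrow = nc, ncol = ns)  # wc fastest
  res <- list()
  if (nc > 1L) {
    diff_v <- ph[-nc, , drop = FALSE] != ph[-1L, , drop = FALSE]
    idx <- which(diff_v, arr.ind = TRUE)
    if (nrow(idx)) {
      res[[length(res) + 1L]] <- data.frame(
        orientation = "vertical",
        wc1 = d$wc_seq[idx[, 1L]], ws1 = d$ws_seq[idx[, 2L]],
        wc2 = d$wc_seq[idx[, 1L] + 1L], ws2 = d$ws_seq[idx[, 2L]],
        phase1 = ph[cbind(idx[, 1L], idx[, 2L])],
        phase2 = ph[cbind(idx[, 1L] + 1L, idx[, 2L])],
        stringsAsFactors = FALSE)
    }
  }
  if (ns > 1L) {
    diff_h <- ph[, -ns, drop = FALSE] != ph[, -1L, drop = FALSE]
    idx <- which(diff_h, arr.ind = TRUE)
    if (nrow(idx)) {
      res[[length(res) + 1L]] <- data.frame(
        orientation = "horizontal",
        wc1 = d$wc_seq[idx[, 1L]], ws1 = d$ws_seq[idx[, 2L]],
        wc2 = d$wc_seq[idx[, 1L]], ws2 = d$ws_seq[idx[, 2L] + 1L],
        phase1 = ph[cbind(idx[, 1L], idx[, 2L])],
        phase2 = ph[cbind(idx[, 1L], idx[, 2L] + 1L)],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(orientation = character(), wc1 = numeric(),
                      ws1 = numeric(), wc2 = numeric(), ws2 = numeric(),
                      phase1 = character(), phase2 = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a phase diagram
#'
#' Writes the cells in long format (`wc,ws,phase,share`) and, next to
#' it, a phase legend `phase,region1..regionK`.
#'
#' @param d A [phase_diagram()].
#' @param path Output path for the cell file; the legend is written to
#'   `<path>` with a `_legend` suffix before the extension.
#' @return Character vector of the two paths, invisibly.
#' @export
write_phase_diagram <- function(d, path) {
  stopifnot(inherits(d, "phase_diagram"))
  write.table(d$cells, path, sep = ",", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  legend_path <- sub("(\\.[^.]*)?$", "_legend\\1", path)
  k <- max(lengths(d$phases))
  legend <- data.frame(phase = names(d$phases), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    legend[[paste0("region", i)]] <-
      vapply(d$phases, function(s) if (length(s) >= i) s[i] else "", "")
  }
  write.table(legend, legend_path, sep = ",", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(path, legend_path))
}
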