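---
title: "Weighted multi-pathway transport connectedness: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multi-pathway transport connectedness: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportrisk)
```

## The problem

Biosecurity agencies of island nations need to know which foreign regions
are most strongly physically connected to them: every inbound ship,
passenger flight and cargo flight is a potential carrier of pests,
pathogens or smuggled wildlife. The three pathways differ enormously in
volume and in per-voyage risk (a species that survives an 8-hour flight
may not survive 15 days at sea), and the appropriate relative weighting
depends on the threat being managed. `transportrisk` implements a simple,
transparent framework for this problem: score each source region by a
*weighted cumulative impact*

$$I = w_p \cdot (\text{passenger flights}) + w_c \cdot (\text{cargo
flights}) + w_s \cdot (\text{ships}),$$

rank regions by $I$, and then study how the ranking behaves as the
weights vary — including integrating it over the whole plausible weight
space to obtain a weighting-free overall hotspot ranking.

The substrate is a *traffic panel*: per (region, year) counts of the
three modes, where a region is a country subdivision
(state/province/territory), or the country itself where no subdivision
exists (Singapore, Hong Kong). Region labels are canonicalised as
`"Country—Subdivision"` and every tie anywhere in the package is broken
by byte-wise (C-locale) label order, which makes all outputs reproducible
bit-for-bit.

## Assumptions

The score is deliberately austere. It assumes per-voyage relative risk is
a property of the *mode* only — identical across routes, seasons and
carriers — so that region risk is linear in voyage counts. It attributes
each voyage to its *last port of call* (the only history routinely
available for ships); multi-stop flights can alternatively be spread
*proportionally* over all foreign stops of the itinerary. Nothing about
species biology, environmental matching, or the traffic's upstream
origin enters the score; such factors belong in complementary models.

Because $I$ is linear, only weight *ratios* matter for rankings:
`rank_regions()` is invariant under positive rescaling of
$(w_p, w_c, w_s)$ (a tested property). We therefore usually pin one
weight at 1.

## Scoring and ranking

`impact_table(panel, year, w)` evaluates $I$ for every region present in
the year; `rank_regions()` orders it (rank 1 = highest). Ties are broken
by ascending label. Ranking with the all-zero weight vector is rejected;
regions present in the panel with zero traffic everywhere are retained
and rank among themselves by label, which keeps ranking denominators
constant across weightings — important when rankings are compared or
aggregated.

```{r example}
panel <- read_panel(system.file("extdata", "table2_2012.csv",
                                package = "transportrisk"))
rank_regions(impact_table(panel, 2012, weight_vector(1, 20, 50)))[1:5, ]
```

Temporal behaviour is summarised by `impact_change_pct()` (percent change
of total impact between two years, exact in reals, no intermediate
rounding) and `rank_trajectory()` (a region's rank recomputed year by
year; years where the region has no panel entry are omitted).

## Phase structure of the weight space

Fixing $w_p$ and varying $(w_c, w_s)$ over a rectangular grid (endpoints
inclusive; default $[0,50]^2$ at step 0.01), `phase_diagram()` records
the top-5 region set at each grid point. Contiguous cells with the same
set form a *phase*; labels A, B, C, … are assigned in scan order
($w_c$ fastest, $w_s$ ascending), deterministically. The top-5 is
compared as a **set** — the scientific question is which regions make
the cut — with an ordered-list mode behind a flag. Each cell also
records the top-5 *share* of total impact (in $[0,1]$, continuous in
the weights wherever the set is constant), a measure of how top-heavy
the ranking is. `extract_boundaries()` lists axis-adjacent cell pairs
with differing sets; at weights lying exactly on a boundary the
deterministic tie-break decides membership, so boundaries are reported
between cells, never at cells.

Two numerical choices deserve comment:

* **Pruning.** The dense grid is quadratic in its resolution, so
  `candidate_prune()` first removes regions that provably cannot reach
  the top 5 anywhere in the non-negative orthant. Weak mode-wise
  domination (≥ in all modes, > in at least one) bounds the dominated
  score but does **not** by itself guarantee a lower *rank*: on boundary
  weightings that zero every mode where the dominator leads, the two
  scores tie and the label tie-break could favour the dominated region.
  A dominator is therefore only counted when it dominates strictly in
  all three modes, or also precedes the region in label order. With
  this refinement, pruned and unpruned diagrams are identical on every
  tested instance (a property exercised on 100+ random panels), while
  typically shrinking a few-hundred-region panel to a handful of
  candidates.
* **Grid convention.** Endpoints are included, so the $w_c = 0$ and
  $w_s = 0$ edges (single- and two-mode scoring) are part of the
  diagram.

## Overall hotspot ranking

To remove the weighting choice entirely, rankings are integrated over a
bounded weight space. The bounds come from a closed-form *infimum
search* (`infimum_weight()`): with the other two weights at 1, the
smallest focal-mode weight beyond which the combined ranking is
consistent with the ranking by that mode alone. Consistency is with the
focal-mode *weak* order (the combined ranking must be a linear extension
of it): many regions are tied at zero on some mode, and under a strict
reading the infimum would not exist. For a pair with focal counts
$m_a > m_b$ and off-mode totals $f_a, f_b$, order is settled for all
$w > (f_b - f_a)/(m_a - m_b)$; the infimum is the largest pairwise
threshold, floored at 1. A grid-scan oracle over the defining predicate
confirms the closed form on random panels.

`sample_weightings()` then draws, for each face of the space (one weight
pinned at 1), `n_per_face` points with the two free weights independent
uniform on $[1, \text{bound}]$ — 30,000 points at the default 10,000 per
face. Uniform-on-$[1,b]$ is our reading of "uniformly chosen
combinations" with all-unique ratios; it is corroborated by reproducing
the published first-place split on the shipped 20-region 2012 fixture
(≈49.5% / ≈50.5% against the printed 49.47% / 50.53%). Continuous draws
make duplicate ratio trios a measure-zero event; a diagnostic attribute
counts any exact collisions. `aggregate_ranking()` ranks all regions at
every point and reports, per region, the *aggregate ranking value* (sum
of rank positions; the floor is the number of points, attained by a
region that is first everywhere) and the percentage of points in the
top 1/5/10/50. Rank mass is conserved — the aggregate values sum to
$N \cdot R(R+1)/2$ — and the top-1 percentages sum to 100, both tested
invariants. Zero-traffic rank ties are resolved by the same label
tie-break; shared ranks are never emitted.

## Synthetic traffic panels

Real inbound-traffic panels are proprietary, so `generate_panel()`
provides a statistically analogous stand-in for testing and method
study. It emulates: heavy-tailed per-mode volumes (log-normal,
integerised half-up); *hub* regions whose volumes are high in all three
modes (a shared latent size factor with correlation `mode_cor = 0.7`
induces the cross-mode association; hubs draw from a `hub_shift = 2.5`
upshifted log-mean); a majority of *single-mode* regions (55% by
default, cycled over the modes — the passenger-only holiday island and
ship-only industrial province archetypes); per-region multiplicative
annual growth (passenger strongest at 5%/yr nominal); and rare shipping
*surge* regions whose last/first-year ship ratio is log-normally spread
around 27× over a 14-year panel — the empirically observed order of
magnitude for fast-industrialising provinces. Default scale parameters
(`volume_meanlog` 4.0/1.8/2.5, `volume_sdlog` 1.6/1.3/1.4) put a
300-region panel at roughly 70,000 flights and 10,000 ship arrivals per
year, the magnitude of national inbound data.

`generate_itineraries()` emits voyage-level records (one port per
region) whose last-port aggregation reproduces the panel *exactly* — a
tested round-trip — with a configurable fraction of two-leg itineraries
so the two flight-attribution conventions genuinely differ.

What the generator does **not** emulate: real geographic route
structure, seasonality within years, correlated growth shocks across
regions, and multi-port ship histories. Tests passing on synthetic
panels therefore establish the *algorithms'* correctness and the
method's behaviour under realistic volume distributions, not claims
about any particular country's traffic; the shipped fixtures of the
published 2012 tables are the real-data anchor.

## Problem sizes and determinism

All randomness flows through explicit seeds (`sample_weightings()`,
`synthetic_config()`), and every ordering is deterministic, so any
result is reproducible from its logged configuration (the CLI writes a
`run_log.txt` per run). The test suite exercises the full 30,000-point
integration on the 20-region fixture (about a second) and keeps
property sweeps at 100 random panels with coarse phase grids; the dense
0.01-step diagram over $[0,50]^2$ (25 million cells) is supported and
is practical after pruning, but a 0.1–1 step is recommended for
interactive exploration.

## Limitations

The framework measures *physical connectedness*, not realised risk:
regions with strict export biosecurity, or whose traffic is mostly
transshipment, will be over-weighted relative to their true threat.
Last-port attribution credits intermediate hubs with upstream traffic
(proportional attribution only partially mitigates this, and only for
single-flight-number itineraries). And the infimum bounds depend on the
panel analysed — bounds derived from a 20-region excerpt differ from
bounds on a full several-hundred-region panel, so bounds should be
recomputed (`compute_bounds()`) for each panel rather than reused.
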