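# transportrisk

Weighted multi-pathway transport connectedness and biosecurity hotspot
ranking.

## What it does

Border biosecurity planning needs to know which foreign source regions
are most strongly physically connected to a focal country through the
transport network — every arriving ship, passenger flight and cargo
flight can carry invasive species, pests or pathogens. `transportrisk`
scores each source region (country subdivision, or country where none
exists) in each year by its **weighted cumulative impact**

```
I = w_p · (# passenger flights) + w_c · (# cargo flights) + w_s · (# ships)
```

where the non-negative weights encode how much more likely one voyage
type is to carry a threat than another (only their ratios matter), and
builds three analyses on top of the score:

* **Ranked impact tables** for any year and weighting, with temporal
  comparisons (total-impact percent change between years, per-region
  rank trajectories).
* **Phase diagrams**: how the *set* of top-5 regions changes over a
  grid of cargo/ship weights at fixed passenger weight, with the top-5
  share of total impact per cell, and a sound domination-based pruning
  step that makes dense grids tractable.
* **Overall hotspot ranking**: closed-form per-mode weight bounds (the
  smallest weight at which one mode alone dictates the ranking),
  uniform sampling of 30,000 weightings over the bounded space, and
  aggregation of rank positions into an integrated, weighting-free
  hotspot summary with top-1/5/10/50 membership percentages.

A synthetic traffic-panel generator (heavy-tailed volumes, all-mode hub
regions, single-mode regions, growth trends and shipping surges) plus a
voyage-level itinerary generator make the whole pipeline testable
without proprietary traffic data; fixtures of published 2012
worked-example tables for traffic into Australia are shipped in
`inst/extdata/` as the real-data anchor.

## Worked example

```r
library(transportrisk)

panel <- read_panel(system.file("extdata", "table2_2012.csv",
                                package = "transportrisk"))

# cargo-heavy scenario: ships 50x, cargo flights 20x a passenger flight
rank_regions(impact_table(panel, 2012, weight_vector(1, 20, 50)))
#>                           region impact rank
#> 1                      Singapore  86332    1
#> 2       New Zealand—North Island  50916    2
#> 3                 China—Shandong  36850    3
#> 4     Taiwan (Province of China)  31284    4
#> 5                  China—Jiangsu  29850    5
#> ...
```

Singapore — a global sea *and* air hub — tops the cargo-heavy ranking;
Shandong reaches rank 3 on ships alone (737 arrivals, no recorded
flights). Under equal weights the ordering is passenger-flight
dominated instead, and the integrated ranking over all sampled
weightings splits first place almost evenly between Singapore and the
North Island of New Zealand:

```r
p4 <- read_panel(system.file("extdata", "table4_2012.csv",
                             package = "transportrisk"))
s  <- sample_weightings(parameter_bounds(68, 1661, 700),
                        n_per_face = 10000, seed = 1)
hs <- aggregate_ranking(p4, 2012, s)
hs[1:2, c("region", "aggregate_rank", "prop_top1")]
#>                     region aggregate_rank prop_top1
#> 1                Singapore          45089  49.97667
#> 2 New Zealand—North Island          46881  50.02333
```

A subcommand CLI (`inst/cli/transportrisk`) wraps the same functions:
`impact`, `phase`, `hotspot`, `temporal`, `simulate`.

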