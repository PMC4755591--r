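Package: transportrisk
Title: Weighted Multi-Pathway Transport Connectedness and Biosecurity
    Hotspot Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies physical transport connectedness between source
    regions and a focal country from region-by-year panels of passenger
    flights, cargo flights and ship arrivals. Computes weighted cumulative
    impact scores and region rankings for arbitrary pathway weightings,
    maps phase changes in the composition of the top-ranked regions across
    weight space, derives per-pathway weight bounds by a closed-form
    infimum search, and integrates rankings over sampled weightings into
    an overall hotspot summary. Includes a synthetic traffic-panel and
    voyage-record generator with heavy-tailed volumes, hub structure,
    single-mode regions and shipping surges, plus a command-line interface
    for batch analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
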