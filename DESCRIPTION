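Package: agroanalogs
Title: Context-Specific Climate Analogs for Agricultural Counties
Version: 0.1.0
Authors@R:
    person("Agro-Climate", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies climate analog counties for agricultural (specialty
    crop) production: derives agro-climatic indices (growing degree days,
    frost-free season length, heat degree hours, chill hours, precipitation
    uniformity) from daily weather, aggregates them over agricultural grid
    cells to county units, scores target-future versus candidate-present
    climate dissimilarity with an interannual-variability-scaled Mahalanobis
    distance expressed on the sigma (chi-distribution percentile) scale,
    forms multi-GCM ensemble consensus analog sets, and compares crop mixes
    of target-analog pairs. A seeded synthetic-data generator emulates
    gridded daily weather, pseudo-GCM projections, land use, county
    partitions and a crop census so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
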