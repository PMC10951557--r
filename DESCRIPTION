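Package: ccre
Title: Climate Contrast Resurrection Ecology Analysis
Version: 0.1.0
Authors@R:
    person("Sandbox", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the Climate Contrast Resurrection Ecology design:
    derive climate-change metrics (means, variability, ranges, seasonal
    precipitation extremes, vapour-pressure-deficit aridity and
    excess-heat-factor style extreme-event durations) from paired
    historic/modern daily weather series, compute per-species
    log-ratio-of-means trait-change effect sizes from paired seed-cohort
    measurements, and relate the two with variance-weighted random-effects
    meta-regression (REML heterogeneity), all-subsets AICc multi-model
    inference with Akaike-weight variable importance, and an
    iterative-PCA/Horn's-parallel-analysis leaf-economics axis.  Includes a
    synthetic-data generator with known ground truth so every stage of the
    pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
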