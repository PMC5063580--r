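Package: wsbsync
Title: Spatial Synchrony Analysis of Multi-Century Insect Outbreak
    Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sub-continental spatial synchrony in annual
    binary outbreak reconstructions of forest defoliators (built around the
    western spruce budworm) and their association with drought indices.
    Converts stand-level percent-of-trees records to regional binary outbreak
    records, detects synchronous outbreak periods across regions, quantifies
    temporal co-occurrence of outbreak events with a one-dimensional
    multivariate Ripley's K-function and circular-shift randomization
    envelopes, measures distance decay of outbreak and climate similarity
    with Mantel and partial Mantel permutation tests, and composites drought
    anomalies around synchronous-outbreak initiations and cessations with
    superposed epoch analysis and Monte-Carlo confidence intervals. A
    synthetic-data generator produces spatially autocorrelated climate with
    an optional northwest/southwest dipole and climate-forced quasi-periodic
    outbreak regimes, so the full pipeline can be exercised and calibrated
    without the original tree-ring archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
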