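Package: savtrends
Title: Trend Analysis of Woody Cover, Vegetation Production and Rainfall
    Climatology in Tropical Savannas
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting structural change in tropical savanna
    ecosystems from gridded time series. Computes annual rainfall-climatology
    indices (annual total, rainy days, heavy-rainfall frequency above the
    baseline 90th percentile, intensity), annual maximum leaf area index and
    annual minimum vegetation optical depth with its woody-cover transform,
    the 15-year moving-window sensitivity of vegetation production to annual
    rainfall, Theil-Sen slopes with autocorrelation-corrected Mann-Kendall
    significance, LMG relative-importance attribution of woody-cover change,
    and rainfall-gradient and quadrant-agreement summaries. Includes a
    stochastic weather and vegetation generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
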