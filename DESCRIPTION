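Package: calffever
Title: Fever Detection in Calves from Ventral Tail-Base Surface Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting fever in beef calves from
    10-minute ventral tail-base surface temperature (ST) records collected by a
    wearable sensor. Implements sensor-trace preprocessing (extreme-value and
    jump filters, hourly-maximum extraction), rhythm-corrected temperature
    transforms (estimated ST, residual ST, estimated residual ST), rule-based
    fever labeling (sustained-elevation run rule), rolling-window
    minimum/maximum feature engineering, a random-forest fever classifier with
    an 80/20 split, repeated k-fold cross-validation and Gini variable
    importance, and the association analysis of surface-temperature
    measurements with rectal temperature. A synthetic-trace generator with a
    diurnal rhythm, fever episodes and sensor artifacts makes every stage
    testable without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
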