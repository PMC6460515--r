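Package: multinomogram
Title: Parallel-Scale Nomograms and Scoring Charts for Multinomial
    Logistic Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs parallel-scale nomograms and standardized
    points-based scoring charts for fitted multinomial logistic
    regression prediction models with any number of outcome categories.
    Computes linear predictors and category probabilities from a
    supplied coefficient table, derives the chart geometry (axis
    scaling factors, middle-axis placement, tick marks) and the 0-100
    points system (rescaling factor, per-covariate points, baseline and
    total points, exponentiated linear-predictor axis), renders
    deterministic SVG drawings with optional case-study isopleth
    overlays, and verifies the geometric reading against the analytic
    probabilities. Ships a published antepartum operative-delivery
    prediction model as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
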