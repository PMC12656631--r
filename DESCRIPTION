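Package: trailpace
Title: Terrain-Weighted Pacing Analysis and Finish-Time Prediction for Trail Races
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing checkpoint split times in mountain trail
    races. Computes terrain difficulty factors and relative difficulty
    coefficients for course sections, converts raw section times into
    difficulty-weighted times, pacing-variability indices and pooled
    checkpoint percentile ranks, compares groups with bootstrap t-tests,
    effect sizes and post hoc power, fits multiple linear regression models
    of finish time with a full diagnostic battery (Durbin-Watson, variance
    inflation, Cook's distance, Bland-Altman agreement), and evaluates
    closed-form in-race finish-time predictors. A synthetic race generator
    reproduces the statistical structure the models assume so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
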