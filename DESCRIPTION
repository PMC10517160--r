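Package: vo2quant
Title: Probabilistic VO2 Max Estimation from Wearable Heart-Rate and
    Step-Count Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates cardiorespiratory fitness (VO2 max) distributions
    from free-living wearable data. Converts irregular heart-rate samples
    and step-count intervals into per-minute series, derives cadence to
    heart-rate ratio quartiles, daily MET-minute quartiles and the
    coefficients of piecewise-linear quantile regressions of heart rate
    on cadence, and feeds the resulting 24-dimensional feature vector
    into a stack of gradient-boosted quantile learners whose outputs are
    monotonized by rearrangement. Includes calibration (expected
    calibration error), sharpness (mean interquartile range) and CRPS
    scoring, cross-validation, ablation experiments, Shapley-value
    feature attribution, and a seeded synthetic wearable-cohort
    generator for end-to-end testing without access to device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
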