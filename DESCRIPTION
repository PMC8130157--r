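Package: lcpower
Title: Empirical Learning Curves and Power-Law Scaling for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures and models the data-scaling behavior of supervised
    regression models, with drug response prediction in cancer cell lines as
    the motivating application. Generates learning-curve data over nested
    training subsets of shuffled train/validation/test splits, fits the
    three-parameter power law s(m) = a*m^b + c by weighted nonlinear least
    squares with quantile variability bands, and forecasts prediction error
    beyond the available training size. Includes preprocessing of raw
    dose-response viability measurements into quality-filtered, dose-range
    normalized AUC labels via the three-parameter Hill-slope model, and a
    synthetic-data module emulating the cell-by-drug cross design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    pracma,
    caret,
    xgboost,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
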