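Package: akibench
Title: Impact of Baseline Creatinine Estimation on AKI Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of baseline serum-creatinine
    estimation method changes KDIGO acute kidney injury (AKI) labelling and,
    through it, the measured performance of clinical prediction models.
    Provides a KDIGO serum-creatinine labelling engine with a brute-force
    reference oracle, six baseline estimators (first-24h minimum, MDRD
    backward calculation variants, and pre-ICU window aggregates), a
    synthetic ICU electronic-health-record generator with a known injected
    AKI process, cohort construction (exclusions, first-24h aggregation,
    missingness filtering, chained-equations imputation, min-max scaling),
    calibrated classifier training with up-sampling confined to
    cross-validation training folds, discrimination and calibration metrics
    (AUC, precision, recall, f1, ECE, Brier score, calibration slope),
    bootstrap with ANOVA and Tukey HSD cross-baseline comparison, and
    break-down / ordering-averaged Shapley attributions for false-positive
    error audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
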