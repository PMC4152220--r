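Package: trauma24
Title: Derivation and Internal Validation of Vital-Signs Models for Early
    Trauma Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive, internally validate and deploy logistic
    prediction models for 24-hour mortality in adult trauma patients from
    routinely recorded vital signs (systolic blood pressure, heart rate,
    Glasgow coma scale). Implements restricted cubic spline bases with
    knots at equally spaced percentiles, hospital-stratified multiple
    imputation by chained equations with Rubin's rules pooling, grouped
    backward selection with joint Wald tests, bootstrap estimation of
    optimism and a linear shrinkage factor, and discrimination and
    calibration metrics (AUROCC, calibration slope, Hosmer-Lemeshow,
    sensitivity cut-off tables) pooled across imputations. Ships the
    published final model as a ready-to-use scorer and a synthetic-cohort
    generator emulating the derivation study's statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
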