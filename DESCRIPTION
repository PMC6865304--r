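Package: digirop
Title: Birth-Based Risk Prediction for Retinopathy of Prematurity Treatment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individualized prediction of the risk of treatment-requiring
    retinopathy of prematurity (ROP) from birth characteristics alone
    (gestational age, sex, and birth-weight standard-deviation score).
    Implements a piecewise log-linear hazard model on the postnatal-age
    time axis with closed-form cumulative risk, the person-time Poisson
    regression pipeline that estimates such models from screening cohorts,
    parametric-bootstrap confidence bands, discrimination and calibration
    validation utilities, an exact piecewise-hazard cohort simulator, and
    screening-schedule tools (suggested first-examination ages, risk
    threshold ages, avoided-visit accounting).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
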