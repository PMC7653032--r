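Package: akitransport
Title: Discrete-Time AKI Risk Prediction and Cross-Site Model Transportability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolkit for hospital-acquired acute kidney injury (AKI) risk
    modelling on common-data-model style electronic health records and for
    assessing how well such models transport across hospital sites. Provides
    KDIGO serum-creatinine staging with discrete-time right-censored labels,
    automated daily feature curation (outlier trimming, one-hot coding,
    cumulative medication exposure, sample-and-hold imputation, derived lab
    deltas and blood-pressure trends), a gradient-boosted discrete-time
    survival classifier with logistic recalibration, discrimination and
    Hosmer-Lemeshow calibration metrics, bootstrap SHAP marginal-effect
    summaries with soft-rank feature-commonality analysis, and an adjusted
    maximum mean discrepancy (adjMMD) framework: a gain-weighted,
    missingness-penalised kernel two-sample statistic that predicts the AUROC
    deterioration of a model transported to a new site, with minimal feature
    set search, transportability regression, random-slope mixed-effect
    generalisation and sample/model-agnostic validation tests. A multi-site
    synthetic EHR simulator with controllable covariate shift and feature
    missingness makes the full pipeline exercisable without access to
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
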