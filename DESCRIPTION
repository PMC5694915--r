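Package: hiiboost
Title: Hemodynamic Instability Prediction for the PICU with Abstaining Boosted Stumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the need for hemodynamic intervention (fluid bolus or
    vasoactive drugs) in pediatric intensive care patients from routinely
    charted vital signs, laboratory values and ventilator parameters. The
    learning core is a boosting ensemble of age-conditioned decision stumps
    that abstain from voting when their feature is missing, so sporadically
    measured variables contribute without imputation. Includes a synthetic
    PICU cohort simulator with age-dependent reference physiology, a clinical
    ingest pipeline (plausibility filtering, invasive/noninvasive blood
    pressure reconciliation, measurement staleness rules), intervention-based
    episode labeling with 24-hour last-value feature extraction, a streaming
    risk-score runtime with per-feature contributions and traffic-light risk
    colors, and an evaluation suite (lead-time AUROC, break-even operating
    point, prevalence-adjusted predictive values, stratified reports and
    age-adjusted single-feature baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
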