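Package: mskrisk
Title: Weight-of-Evidence Risk Modeling for Post-Concussion
    Musculoskeletal Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds calibrated risk models for musculoskeletal injury in
    the year after a sports-related concussion from heterogeneous clinical
    cohorts.  Continuous and categorical predictors with heavy missingness
    are discretized by Information-Value-optimal supervised binning and
    recoded as Weights of Evidence (missing values get their own bin, so
    imputation is implicit); variables are then selected along an
    L1-penalized logistic regression path scored by the small-sample
    corrected Akaike Information Criterion, and the selected set is refit
    with an L2 penalty.  Closed-form SHAP attributions, discrimination and
    operating-point metrics, a repeated stratified-split stability
    experiment, and a synthetic cohort generator with known ground truth
    complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
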