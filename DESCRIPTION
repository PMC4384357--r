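Package: batchsurv
Title: Batch-Aware Cross-Validation for Prognostic Survival Biomarker Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, cross-validates, selects and externally validates
    prognostic Cox survival models combining batch-processed RT-qPCR gene
    expression measurements with clinical covariates. Provides two
    cross-validation schemes (outcome-stratified patient-level resampling and
    PCR-batch-level resampling), censored-survival performance indicators
    (IPCW Brier score, Harrell concordance, cumulative/dynamic time-dependent
    sensitivity, specificity and AUC) with pooled and averaged estimation,
    model-selection diagnostics (Kuncheva stability, selection frequency,
    optimism, omitted-covariate impact), penalized Cox model families (lasso,
    adaptive lasso, SCAD, selection-then-refit), fractional-polynomial
    covariate modelling, sample-size planning from the Schoenfeld events
    formula, and a synthetic cohort generator with batch-level technical
    shifts and unbalanced batch event rates for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    glmnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
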