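Package: htradiomics
Title: Multiregional MRI Radiomics for Predicting Hemorrhagic
    Transformation After Stroke Thrombolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for pretreatment prediction of
    hemorrhagic transformation (HT) after intravenous thrombolysis in acute
    ischemic stroke from multiparametric MRI (ADC, CBF, CBV, MTT, TTP).
    Generates fully synthetic cohorts (bilaterally symmetric vascular-territory
    atlas, unilateral infarct and hypoperfusion lesions, five parametric maps,
    Table-1-style clinical covariates), builds 20 bilateral vascular-territory
    regions of interest by lesion intersection and contralateral mirroring,
    extracts 54 radiomics features (18 first-order, 14 shape, 22 gray-level
    co-occurrence matrix) per region and sequence (5400 per patient), ranks
    features by LASSO, screens clinical factors by exact tests and univariate
    AUC, and compares clinical, abnormal-side, all-region and combined random
    forest models with SMOTE rebalancing, five-fold cross-validation and
    held-out validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    ranger,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
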