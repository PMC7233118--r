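Package: radnode
Title: Radiomics Pipeline for Lymph-Node Restaging After Neoadjuvant
    Therapy in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible radiomics analysis for predicting
    pathological lymph-node status after neoadjuvant therapy in locally
    advanced rectal cancer. Provides a synthetic multi-sequence MRI cohort
    generator, 2D first-order/GLCM/GLSZM feature extraction with a
    Laplacian-of-Gaussian filter bank, min-max normalization fitted on the
    primary cohort, a three-step feature-selection chain (Wilcoxon screen,
    Spearman pruning, LASSO with the one-standard-error rule), logistic
    radiomic-signature and combined clinical models with a nomogram export,
    and a model-evaluation suite (DeLong AUC inference, Youden cutoffs,
    Clopper-Pearson confusion metrics, McNemar, continuous NRI,
    Hosmer-Lemeshow calibration, decision curves, Cohen's kappa, and
    stratified subgroup reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
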