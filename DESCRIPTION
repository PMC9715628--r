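Package: methpanel
Title: Minimal DNA Methylation Biomarker Panels from Multi-Omics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for reducing hundreds of candidate multi-omics
    features to a minimal CpG methylation panel that predicts a binary
    disease phenotype. Provides a synthetic multi-omics cohort generator
    with planted ground truth, elastic-net penalized logistic
    classification with frozen standardization for cross-cohort
    replication, ten-times repeated stratified k-fold cross-validation
    with minority upsampling, rank-product aggregation of per-run feature
    importances, incremental panel construction stopped by the corrected
    repeated k-fold cross-validation test, sequential data-layer
    contribution analysis, and downstream interpretation statistics:
    eQTM and MeQTL linear-model scans with false discovery rate control,
    stratified group contrasts, and quasi-Bayesian causal mediation
    analysis reporting the proportion of a genetic effect mediated by
    methylation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
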