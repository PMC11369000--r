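Package: steroidpanel
Title: Sex- and Severity-Stratified Analysis of Plasma Steroid Hormone Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for a nine-analyte plasma steroid hormone
    panel measured in cohorts stratified by sex and ME/CFS disease severity.
    Provides a Gaussian-copula synthetic cohort generator quantile-matched to
    published median/IQR summaries, normality-gated univariate group testing
    with Benjamini-Hochberg and Benjamini-Yekutieli false discovery rate
    control, Spearman correlation matrices compared by a permutation variant
    of Jennrich's test, leave-one-out classifier evaluation (LDA, random
    forest, PLS-DA) with ROC curves and closest-to-(0,1) optimal cutpoints,
    and unsupervised structure analysis (PCA, Euclidean hierarchical
    clustering with heatmap export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
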