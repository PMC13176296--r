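Package: twascore
Title: Per-Cell TWAS Activity Scoring, Stratification and Signature Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every cell of a single-cell RNA-seq experiment for the composite
    activity of a genetic risk-gene set derived from a transcriptome-wide association
    study (TWAS). Five independent gene-set statistics (expression-matched module score,
    AUCell-type recovery area, UCell-type Mann-Whitney rank score, singscore-type mean
    normalized rank, and a single-sample weighted Kolmogorov-Smirnov enrichment) are
    normalized and summed into a composite activity score; cells are stratified into
    low/median/high activity states by quartiles, group enrichment is quantified by the
    ratio of observed to expected cell numbers (Ro/e), a consensus signature is derived
    by intersecting seven feature selectors (LASSO, random forest, XGBoost, gradient
    boosting, a shadow-feature Boruta procedure, decision tree, and adaptive best-subset
    selection), and the signature is evaluated with patient-grouped nested and
    leave-one-patient-out cross-validation. A synthetic-data module generates
    negative-binomial expression data with planted active subpopulations and TWAS
    summary-statistic fixtures with planted causal genes, so the whole pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    ranger,
    xgboost,
    rpart,
    e1071,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
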