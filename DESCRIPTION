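Package: exoscreen
Title: Machine-Learning Screening of Exosome RNA Diagnostic Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, testable implementation of a liquid-biopsy biomarker
    screening strategy for exosome RNA expression cohorts. Starting from a
    feature-by-sample count matrix, the pipeline applies prevalence and
    abundance filtering, log2(CPM+1) normalization, RNA-type stratum
    harmonization, and negative-binomial Wald differential expression with a
    triple screening gate; candidate features are then ranked by ensemble
    stability selection (L1-penalized logistic regression, random-forest
    impurity importance, and linear-SVM recursive feature elimination) with
    resampling stability scores and outer-fold consistency scores, and the
    consensus panel is evaluated by leakage-safe nested cross-validation with
    SMOTE class rebalancing, RBF-SVM grid search, fold-based AUC confidence
    intervals, calibration assessment (Hosmer-Lemeshow, Brier score,
    calibration slope), external-cohort validation with linear classifiers,
    cross-cancer specificity panels, and local hypergeometric gene-set
    enrichment. A synthetic-cohort generator with planted biomarkers provides
    a ground-truth test surface so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    withr,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    edgeR,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
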