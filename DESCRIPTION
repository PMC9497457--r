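Package: m6aPatterns
Title: Molecular Patterns, Diagnostic Models and Immune Profiling for
    RNA-Methylation Regulators in Case/Control Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for discovering molecular
    patterns mediated by epitranscriptomic (m6A/m5C) regulator genes in
    case/control expression cohorts: multi-batch merging with
    empirical-Bayes batch correction, rank-based differential testing, a
    two-stage (univariate logistic + LASSO) diagnostic model with ROC/AUC
    and Hosmer-Lemeshow calibration, resampled consensus clustering with
    PAC-based selection of the number of clusters, single-sample gene-set
    enrichment (ssGSEA and GSVA) for immune-microenvironment profiling,
    correlation-threshold selection of regulator-linked lncRNAs, weighted
    co-expression modules, and a PCA-derived per-sample methylation score.
    Includes a synthetic-cohort generator that emulates the merged
    multi-batch case/control study design so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
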