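Package: ucSubtype
Title: Molecular Subtyping of Ulcerative Colitis by Ferroptosis and
    Neutrophil Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies ulcerative-colitis mucosal transcriptomes into four
    molecular subtypes (quiescent, ferroptotic, neutrophilic, mixed) from the
    signs of per-sample median z-scores over a ferroptosis and a neutrophil
    gene program. Provides resampling consensus clustering for curating
    co-expressed signature genes, ssGSEA and marker-mean immune scoring,
    weighted co-expression network modules with eigengene-trait correlation,
    preranked GSEA and hypergeometric over-representation, an ensemble of
    five feature selectors (Boruta, L1 logistic regression, SVM-RFE, random
    forest, gradient boosting) whose intersection yields diagnostic hub
    genes, and a binarized-score feedforward network diagnostic evaluated by
    ROC, confusion matrix and Hosmer-Lemeshow calibration. A seeded
    multi-batch cohort simulator with planted co-expression programs, latent
    subtypes, diagnostic genes and responder coupling supplies ground truth
    for testing every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    sva,
    glmnet,
    e1071,
    randomForest,
    ranger,
    xgboost,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
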