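Package: pcmbench
Title: Proteochemometric and Multi-Task QSAR Bioactivity Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for benchmarking bioactivity models on ChEMBL-style
    compound-target activity tables. Covers data curation (confidence,
    target-type and provenance filters, median aggregation of duplicate
    measurements, activity labelling at a configurable pChEMBL threshold),
    compound featurisation (hashed circular fingerprints and physicochemical
    properties via OpenBabel), alignment-free protein descriptors (169
    physicochemical sequence features), classical learners (naive Bayes with
    z-score background correction, random forest, support vector machine,
    logistic regression) and feed-forward neural networks in single-task,
    multi-task and proteochemometric modes with a masked regression loss.
    Validation uses random semi-stratified and temporal splits scored by MCC
    and BEDROC, cross-method z-score ranking with pairwise statistical tests,
    grid search over network configurations, majority/average-vote ensembles,
    and a synthetic ChEMBL-like data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
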