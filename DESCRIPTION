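Package: emrgraph
Title: Heterogeneous Patient Graphs and HinSAGE Link Prediction from
    Electronic Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns electronic medical record (EMR) style tables into two
    graph representations of a cardiovascular cohort: a patient-centric
    heterogeneous property graph (10 node types, 9 edge types, with Cypher
    bulk-import and GraphML export) and a learning-ready bipartite
    patient-diagnosis graph with fixed-length node features and a binary
    five-year composite event outcome on each edge.  Includes a synthetic
    EMR generator for an angina admission cohort, inclusion/exclusion
    cohort selection with outcome labelling, a from-scratch heterogeneous
    GraphSAGE (HinSAGE) model for supervised link-attribute inference, and
    evaluation with AUROC/AUPRC, stratified bootstrap confidence intervals
    and random-forest, logistic-regression and neural-network baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml,
    randomForest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
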