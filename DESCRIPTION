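Package: AdhereNet
Title: Predicting Adherence to Mental Training from Resting-State Connectome Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic analysis of resting-state functional connectomes
    for predicting participant adherence to mental training programs. Builds
    pairwise Pearson connectivity graphs from parcellated ROI time series,
    binarizes them over a sparsity threshold sweep, and computes nodal and
    global network metrics (clustering coefficient, local and global
    efficiency, degree centrality, Louvain modularity, and a binarized
    system-segregation index over canonical resting-state networks). Metrics
    are related to adherence scores through permutation correlation tests
    with Benjamini-Hochberg false-discovery-rate control across nodes and
    thresholds, and high versus low adherence is classified with four
    machine-learning methods under leave-one-out cross-validation with
    backward feature elimination. A synthetic cohort generator with planted
    modular covariance coupled to adherence makes the full pipeline testable
    without access to neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Rcpp,
    randomForest,
    rpart,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
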