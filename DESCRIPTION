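Package: gefdriver
Title: Cancer Driver Gene Identification from PPI Networks and Multi-Omics
    Features via Graph-Enhanced Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised identification of cancer driver genes on
    protein-protein interaction (PPI) networks with multi-omics node
    features. Each gene receives two embeddings learned from the same
    graph, one by spectral graph convolution and one by multi-head graph
    attention; their concatenation (the graph-enhanced feature) is
    classified by a small multilayer perceptron trained with a
    class-weighted cross-entropy loss. Candidate driver genes are called
    by intersecting top-K rankings across several PPI networks. Includes
    readers and writers for edge lists, feature tables and label lists, a
    synthetic-data generator with planted driver communities for offline
    validation, and evaluation metrics for imbalanced classification
    (AUROC, AUPR, MCC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
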