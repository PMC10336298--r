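Package: graphMLM
Title: Multi-Network Gene Embedding via Masked Language Modelling over
    Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised integration of weighted gene networks by
    converting each network into "sentences" of nodes via weight-biased
    random walks and training a small transformer encoder with a
    masked-node prediction objective. Once per epoch the shared node
    embedding table is smoothed over one of the input networks by a
    single random-walk-with-restart propagation step, which regularises
    the embedding towards the graph structure. The learned node
    embeddings support gene module detection (hierarchical clustering
    scored by adjusted mutual information) and multi-label gene function
    prediction (random forests, macro F1), and the [CLS] sequence
    embedding supports pathway-level classification of labelled paths.
    Includes deterministic stochastic-block-model generators for
    multi-network collections with planted modules and labelled paths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    randomForest,
    pROC,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'encoder-ops.R'
    'network-io.R'
    'walks.R'
    'train.R'
    'evaluation.R'
    'graphMLM-package.R'
    'synthetic.R'
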