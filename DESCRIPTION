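Package: hyperspot
Title: Spatial-Domain Segmentation of Spatial Transcriptomics via Hypergraph Convolutional Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised joint embedding of spatial transcriptomics data for
    spatial-domain segmentation. Gene expression is encoded by a deep
    autoencoder and spatial context by a two-layer variational hypergraph
    convolutional encoder built on a k-nearest-neighbour hypergraph of spot
    coordinates; the concatenated embedding is refined with a deep embedded
    clustering (DEC) objective and a pairwise spatial regularizer. Includes
    readers for common expression-matrix formats, a synthetic tissue
    simulator with planted spatial domains and marker genes, Leiden-based
    segmentation with a target cluster count, clustering evaluation metrics
    (adjusted Rand index, normalized mutual information, label Moran's
    index), and one-vs-rest marker-gene ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
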