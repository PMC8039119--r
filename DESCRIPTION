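Package: miglia
Title: Single-Cell Microglia Transcriptomics and Skeleton Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for droplet single-cell RNA-seq analysis of
    brain immune cells: barcode knee selection, median-absolute-deviation
    quality filtering (2-of-3 rule), gene filtering, library-size
    log-normalization, highly-variable-gene selection, PCA, shared-nearest-
    neighbor Louvain clustering with silhouette-based resolution selection,
    marker-panel cluster annotation, contaminant purification of a target
    population, covariate-adjusted differential expression (hurdle tests and
    negative-binomial GLMs), gene-signature overlap and direction
    concordance, and microglia skeleton morphometrics (process length,
    branch points, segments) with the accompanying group statistics. A
    synthetic droplet-data generator with planted ground truth provides a
    download-free test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
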