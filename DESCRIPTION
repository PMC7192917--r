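Package: adiponet
Title: Connectivity-Constrained Subnetwork Decomposition of Single-Cell
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes z-scored single-cell RNA-seq expression matrices
    into ranked rank-1 network modules whose gene supports induce connected
    subgraphs of a protein-protein interaction network, and links clonal
    bulk RNA-seq metabolic phenotypes to single-cell clusters by projecting
    per-gene Spearman phenotype-correlation vectors onto individual cells.
    Includes QC and normalization for UMI count matrices, a SIF network
    reader, clone clustering with silhouette-based model selection,
    extreme-clone phenotype tests, and a synthetic-data generator with
    planted connected modules for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
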