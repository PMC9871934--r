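Package: orthocell
Title: Cross-Species Cell-Type Homology Mapping for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative single-cell RNA-seq analysis
    of two species: quality control (gene/cell filters, mitochondrial
    fraction, artificial-doublet kNN scoring), log-normalization,
    highly-variable-gene selection, PCA, kNN-graph community detection,
    one-vs-rest Wilcoxon marker detection, cross-species cell-type
    correspondence via ortholog top-marker intersection and hierarchical
    clustering of scaled pseudobulk profiles, gene-set module scoring, and
    hypergeometric gene-set enrichment. Includes a two-species synthetic
    count generator with planted cell-type homology, composition shifts,
    mitochondrial content and doublets, used as ground truth in tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    igraph,
    Rtsne,
    ape,
    fgsea,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
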