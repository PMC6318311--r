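Package: natalung
Title: Cell-Type Atlas Workflow for Droplet Single-Cell RNA-Seq of the Newborn Lung
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end analysis workflow for droplet-based
    single-cell RNA-seq count matrices of the kind used to build a cell atlas
    of the newborn mouse lung: cell and gene quality-control filters,
    library-size normalization with negative-control-gene batch scaling,
    iterative graph-based clustering (highly variable gene selection, PCA
    with standard-deviation thresholded component selection, empirical-Bayes
    batch correction at the subtype level, Jaccard-weighted k-nearest-neighbour
    Louvain community detection, doublet-cluster flagging, marker-based cell
    type assignment, and a cell-type dendrogram), and the per-gene statistics
    used to call markers: a one-tailed binomial expression-frequency test with
    effective size and false discovery rate, signature-gene selection,
    a sensitivity-based enrichment score, Welch t differential expression for
    plate data, one-tailed Fisher gene by cell-type association, and
    chi-square with Yates continuity correction. A synthetic Drop-seq data
    generator with ground-truth labels (cell types with nested subtypes,
    multiplicative batch effects, log-normal library sizes, over-dispersed
    counts, mitochondrial and negative-control genes, doublets) makes every
    stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    sva,
    Rtsne,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
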