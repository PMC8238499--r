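Package: multiweave
Title: Weighted Nearest Neighbor Integration of Multimodal Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates two or more simultaneously measured single-cell
    modalities (e.g. CITE-seq RNA + surface protein, or RNA + ATAC) into a
    single graph representation using per-cell modality weights derived from
    within- and cross-modality neighborhood predictions. Provides per-modality
    normalization (log-normalization, centered log-ratio, TF-IDF) and
    dimensional reduction (PCA, LSI), exact and approximate k-nearest-neighbor
    graphs with Jaccard shared-neighbor similarities and adaptive kernel
    bandwidths, the weighted-nearest-neighbor (WNN) graph itself, supervised
    PCA against the WNN graph kernel for reference mapping with mutual
    nearest-neighbor anchors and weighted-vote label transfer, evaluation
    utilities (noise-robustness, cross-cluster edge counts, neighborhood
    homogeneity, perturbation scores, marker-panel selection), and a seeded
    synthetic multimodal data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    irlba,
    RANN,
    igraph,
    glmnet,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    uwot,
    RSpectra,
    rhdf5,
    jsonlite,
    withr,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
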