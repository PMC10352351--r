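Package: fastruv
Title: Multi-Level Removal of Unwanted Variation for Multi-Sample Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes multi-level unwanted (batch, cohort, study) variation from
    multi-sample, multi-condition single-cell expression matrices. Estimates a
    RUV-III factor model on a pseudo-bulk sketch of the data: cells are grouped
    within each batch by graph clustering or supplied cell-type labels,
    pseudo-bulk profiles are built per group, pseudo-replicates are identified
    across batches with a mutual-nearest-cluster graph (optionally within each
    condition), and the unwanted-variation term is estimated from stably
    expressed genes and subtracted to return a fully adjusted expression
    matrix. Supports hierarchical (multi-level) merging trees for atlas-scale
    integration, a negative-binomial simulator with planted batch effects and
    differential-state genes, and evaluation metrics (ARI, silhouette width,
    PCA scores, moderated differential-state testing with FDR/TPR/F1 scoring).
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    limma,
    cluster,
    RANN,
    irlba,
    rhdf5,
    MASS,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
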