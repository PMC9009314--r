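Package: phyloConcord
Title: Concordance of Genetic Ancestry and Gene Expression States in
    Single-Cell Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of genetic ancestry and gene-expression state in
    tumor single-cell RNA-seq data. Estimates the beta parameter of Aldous'
    beta-splitting model to classify cell-phylogeny shape, partitions rooted
    cell phylogenies into genetic ancestries (clade-based annotation for
    balanced and ladder-like trees), quantifies agreement between ancestry
    annotations from different phylogenies (Cramer's V, chi-square, consensus
    annotation), and measures the concordance between genetic ancestries and
    expression states along a deterministic expression trajectory (principal
    components plus minimum spanning tree) via per-ancestry sub-concordance
    indices (SCI) and a whole-tumor overall concordance index (OCI) across a
    sweep of differential-gene scales. Includes SNV and cell quality filters
    for genotype matrices derived from scRNA-seq variant calls, and a seeded
    simulator of coupled phylogenies, genotype matrices and expression
    matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    rlang,
    ape,
    Matrix,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
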