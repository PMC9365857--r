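Package: scModuleMap
Title: Mapping Co-Expression Modules of Trans-eQTL Targets to Rare
    Single-Cell Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether a set of trans-eQTL target genes
    forms a co-expression network that is specific to a rare
    transcriptional cell cluster in multi-sample single-cell RNA-seq.
    Implements droplet and cell quality control, per-sample pseudo-bulk
    aggregation with TMM normalisation, signed weighted co-expression
    network analysis (soft threshold selection, topological overlap,
    dynamic tree cut, module eigengenes, module-trait statistics, hub
    genes), graph-based cell clustering with a marker-AUC merge rule,
    two-part hurdle marker tests, preranked gene set enrichment with a
    gene-set-sampling null, hub-gene sample grouping with a permutation
    null, auxiliary-module preservation (cor.kME), per-cluster
    variability tables, a cross-dataset variance permutation test,
    empirical-Bayes moderated abundance scans, and kNN-neighbourhood
    differential abundance with a spatial FDR. A negative-binomial
    cohort simulator with planted modules, driver activity and
    driver-coupled rare-cluster abundance provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    edgeR,
    limma,
    igraph,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
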