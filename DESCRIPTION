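Package: marrowNiche
Title: Integrated Prioritization of Bone-Marrow Plasma-Cell Survival Factors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates secretome proteomics with protein-protein interaction
    networks and bulk RNA-seq differential expression to prioritize candidate
    stromal survival factors for bone-marrow long-lived plasma cells.
    Provides target-decoy PSM filtering and fraction set algebra for secretome
    protein lists, first-neighbor interactome expansion, a TMM/log-CPM/ANOVA
    differential-expression core with principal-component variance attribution
    and batch adjustment, candidate ranking by differentially expressed
    interaction partners, pre-ranked gene-set enrichment with permutation FDR,
    gene-set eigengene summarization with Ward clustering, Elispot
    survival-curve statistics, and a synthetic-data generator with planted
    ground truth that makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    withr,
    jsonlite,
    yaml,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, Transcriptomics, NetworkInference, GeneSetEnrichment,
    DifferentialExpression, Software
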