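Package: mpadecomp
Title: Multi-Phenotype Association Decomposition and Signature
    Clustering for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-GWAS characterisation of multi-phenotype association
    (MPA) signatures.  Takes per-SNP, per-phenotype GWAS summary
    statistics, selects significant associations with a hierarchical
    Benjamini-Hochberg / Gavrilov-Benjamini-Sarkar false discovery rate
    procedure, maps SNPs into gene regions, and decomposes the resulting
    gene-phenotype relation into gene-module and module-phenotype
    bipartite networks.  Association modules -- maximal sets of SNPs
    sharing an identical significant-phenotype profile, found by
    thresholding the Proportional Similarity (Czekanowski) index at 1
    and clustering with Markov Clustering (MCL) -- form the axes of a
    "powerset space" into which genes are mapped, classified (single-
    phenotype, Type 1, Type 2, complex) and clustered by their detailed
    association signatures.  Includes asymmetric-MAD outlier screening
    for phenotype intensity matrices, a synthetic-data generator with
    planted signatures for end-to-end validation, and exporters for
    sparse-matrix and network interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
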