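Package: lincberry
Title: Long Noncoding RNA Discovery, Expression Landscape and miRNA
    Target-Mimic Analysis for Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of a genome-wide plant lncRNA
    analysis workflow: identification of long noncoding RNAs from assembled
    transcript models (length filter, strand-aware positional classification
    into intergenic, intronic and antisense classes, ORF-based coding
    potential filtering), TMM/CPM expression normalization with
    presence filtering and temporal pattern calling, lightweight weighted
    co-expression modules with eigengenes and hypergeometric term
    enrichment, a plant miRNA target and endogenous target-mimic scanner
    with duplex energies and canonical cleavage prediction, and 5' RLM-RACE
    cleavage-offset tallying. Ships seeded synthetic-data generators that
    plant ground truth for every stage so recovery can be asserted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
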