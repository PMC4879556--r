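Package: discoex
Title: Discriminative Gene Co-Expression Networks with Promoter Motif
    Discovery and GO Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting condition-specific transcriptional
    programs from large expression compendia. Arrays that discriminate a
    biological process are selected by scoring, per array, the fraction of
    a positive gene list falling into the extreme expression quantiles; a
    Pearson-thresholded co-expression network is then built over a
    candidate (responsive) gene set on the selected arrays and gene
    clusters are extracted as connected components. Cluster promoters are
    analysed with a zero-or-one-occurrence-per-sequence (ZOOPS)
    expectation-maximization motif finder against an order-k Markov
    background, discovered motifs are compared to known transcription
    factor binding site models, promoters are scanned for IUPAC consensus
    elements on both strands, and clusters are tested for GO-term
    over-representation with a right-sided hypergeometric test under
    Bonferroni step-down (Holm) correction. Synthetic-data generators with
    ground-truth labels make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    limma,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
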