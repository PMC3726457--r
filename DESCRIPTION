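Package: novtx
Title: Triage and Prioritization of Unannotated Transcripts from RNA-Seq Gene Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging RNA-seq transcript models that overlap no
    annotated gene or pseudogene into prioritized, putatively species-specific
    candidates. Implements a four-filter prioritization cascade (read depth,
    distance to the nearest annotated feature, exon count, and tissue-restricted
    expression detected with the Grubbs extreme studentized deviate test),
    six-frame translation with a minimum open reading frame rule, triage of
    tabular homology-search hits into annotation categories, primer quality
    control with legacy nearest-neighbor melting temperatures and in-silico PCR
    specificity checks, and locus-level conserved-synteny scoring (ortholog
    fractions, gene-order inversion detection, alignment coverage). A synthetic
    cohort generator with planted ground truth emulates the statistical shape of
    the motivating equine data set so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
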