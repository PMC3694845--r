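Package: methgate
Title: Methylation-Gated Transcription-Factor Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for studying how DNA methylation gates the
    transcriptional response to an inducible transcription factor (Gata4) in
    embryonic stem cells and Flk1+ mesoderm progenitors. Provides time-course
    microarray processing (quantile normalization, probe-to-gene merging,
    empirical-Bayes moderated t-statistics), the three-way fold-change Venn
    cascade that defines methylation-dependent hyper-responsive gene sets,
    average-linkage clustering of temporal response profiles, kernel-density
    ChIP-seq peak calling with background enrichment and nearest-gene
    association, central motif-enrichment statistics, and bisulfite clone
    alignment with per-CpG methylation scoring. A synthetic-data generator
    with planted ground truth emulates the study design so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
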