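Package: tfsig
Title: Transcription-Factor Target-Gene Signatures from ChIP-seq and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq peak sets with RNA-seq
    expression tables to derive cytokine-driven target-gene signatures, as used
    to characterise STAT5 targets in natural killer cells. Implements RPKM
    preprocessing with a pooled-median offset, fold-change and p-value based
    differential-expression calling with a built-in exact conditional
    negative-binomial test, window-based peak-to-gene assignment,
    condition-comparative peak analytics (shared/unique peaks, TSS-distance
    and amplitude profiles, two-factor co-occupancy), two-tier (full/compact)
    signature derivation with bound-versus-responsive summary statistics, a
    weighted Kolmogorov-Smirnov gene-set enrichment analysis with a gene-set
    permutation null, and a synthetic-data generator that plants ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    fgsea,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
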