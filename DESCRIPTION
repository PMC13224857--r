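Package: alleloop
Title: Allele-Resolved 4C-seq Contact Quantification and Companion Assays
Version: 0.1.0
Authors@R:
    person("Maarten", "Veldhuis", email = "m.veldhuis@example.org",
           role = c("aut", "cre"))
Description: Quantifies enhancer-promoter contact frequencies from viewpoint
    (4C-seq) sequencing libraries in an allele-resolved manner, as used to
    study regulatory loops in F1 hybrid (129 x CAST) mouse embryonic stem
    cells. Builds double-digest restriction fragment maps, demultiplexes and
    trims viewpoint reads, splits reads by allele-discriminating variants,
    counts ligation junctions per fragment, and produces library-normalized,
    smoothed contact tracks with region-level quantification. Companion
    modules cover allele assignment by alignment score, allelic-imbalance
    testing, per-CpG bisulfite methylation ratios, delta-delta-Ct qPCR
    statistics with mixed-model tests, and smFISH spot detection with
    transcription-site classification. A synthetic-data module generates a
    diploid toy locus and simulated libraries with known ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    lme4,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
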