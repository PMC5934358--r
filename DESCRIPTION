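Package: snoproc5
Title: Co-Transcriptional 5' End Processing Analysis of Yeast snoRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse Rnt1-dependent 5' end processing of
    independently transcribed snoRNA in budding yeast. Detects Rnt1
    cleavage structures (stem-loops capped by AGNN tetraloops) in
    pre-snoRNA 5' extensions, co-localizes them with NET-seq nascent
    3' end signal, builds loop-anchored and mature-3'-end-anchored
    metagene profiles with WT-normalized mutant coverage, classifies
    genes with unprocessed oligoadenylated 3' extensions, parses
    circular RT-PCR clones into junction/extension/oligo(A) calls, and
    scores rRNA 2'-O-methylation from low-dNTP reverse transcription
    qPCR threshold cycles. A deterministic synthetic-data generator
    with planted ground truth makes every stage testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
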