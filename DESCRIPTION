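Package: tailless
Title: Hominoid-Specific Variant Screening and Inverted Repeat Pair Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics screen behind hominoid
    tail-loss analyses: calling lineage-specific SNVs, insertions and
    deletions from multi-species alignment (MAF) blocks using an
    ingroup/outgroup partition; triaging coding consequences of the calls
    against transcript models with SIFT/PolyPhen damaging filters; scanning
    gene loci for exon-flanking inverted intronic repeat pairs (such as
    inverted Alu pairs) scored by stem identity and inner distance, with
    exon-skip reading-frame prediction; and Mendelian cross statistics
    (penetrance with exact binomial intervals, Punnett expectations,
    goodness-of-fit). A seeded synthetic-data module generates alignments,
    loci and crosses with ground-truth manifests so every stage is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
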