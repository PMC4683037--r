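Package: germir
Title: Small RNA Annotation, miRNA Hairpin Discovery and Target Analysis for Germinating Seed Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline modelled on
    miRNA studies of germinating rice seed embryos. Classifies collapsed
    18-30 nt reads against rRNA/tRNA/snoRNA/snRNA references and a known-miRNA
    catalog, discovers novel miRNA hairpins from genomic windows using the
    minimal folding free energy index (MFEI) and star-strand evidence,
    quantifies expression as transcripts per million (TPM) with
    max-normalized differential calls, predicts miRNA targets with a
    six-rule complementarity scorer, confirms cleavage sites against
    degradome tags with a per-site binomial test, and computes
    efficiency-corrected stem-loop RT-PCR ratios. A fully instrumented
    synthetic data generator with ground-truth bookkeeping makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
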