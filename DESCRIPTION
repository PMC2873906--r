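Package: editscan
Title: Detecting RNA and DNA Editing Signatures and Systematic Errors in
    Capillary Sequencing Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans capillary sequencing traces aligned to a reference genome
    for clusters ("runs") of same-type mismatches, the hallmark of ADAR A-to-I
    RNA editing and APOBEC DNA editing. Separates a systematic dye sub-peak
    G-to-A base-calling artifact (AGA-to-AAA / AGG-to-AAG) from genuine editing
    candidates using phred-quality enrichment, flags artifact traces by motif
    and by an alternate-basecall single-offset test, and quantifies enrichment
    with exact statistics (log-space two-sided Fisher test, binomial interval
    overlap, upstream-context profiles, SNP monomorphism). A seeded simulator
    generates reference genomes and trace cohorts with planted editing
    clusters, artifact traces and phred-calibrated background error, with full
    truth tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
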