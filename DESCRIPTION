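Package: tufscan
Title: Detection and Correction of Thermodynamically Ultra-Fastened Genome
    Regions in SNP Array Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-scale GC/CpG wave correction of SNP-array log R ratio
    (LRR) intensities, detection of weak-signal ("Thermodynamically
    Ultra-Fastened", TUF) genome regions anchored by extreme-GC sequence
    elements, per-sample nick-rate estimation from suppression-versus-
    distance decay, association of per-sample wave statistics with
    paralogue ratio test (PRT) amplification ratios, an in-silico
    fragmentation advisor for restoring amplification of TUF-flanked
    amplicons, and a mechanistic synthetic-cohort generator with full
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    limma,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
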