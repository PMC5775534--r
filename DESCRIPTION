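Package: retrosilence
Title: Retroelement Expression, Methylation and Peak-Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies endogenous retrovirus (ERV/IAP) activation from
    repeat-aware RNA-seq counting under inclusive (random-placement
    multi-mapper) and unique mapping regimes, builds a merged repeat
    annotation from RepeatMasker output with full-length classification,
    performs negative-binomial differential expression with a
    twofold/p<0.05 call rule, calls per-CpG 5mC and 5hmC levels from
    paired bisulfite/oxidative-bisulfite amplicon reads, and tests
    ChIP-seq peak enrichment over repeat classes against a shuffled-peak
    null restricted to mappable regions. Ships a synthetic-data generator
    with full ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
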