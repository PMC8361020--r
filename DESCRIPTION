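Package: hskit
Title: Detection and Prevention of Heterosplicing in Heterologous Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for diagnosing and preventing cryptic ("hetero") splicing of
    heterologous cDNAs expressed in Physcomitrium patens and similar hosts.
    Implements codon-usage-driven synonymous CDS optimization for two-fold
    degenerate amino acids, genome-wide splice-site motif profiling from
    FASTA/GFF3 annotation, PWM-based cryptic intron detection with in-silico
    splicing, translation, tryptic digestion and protein mass prediction, and a
    3-D confocal fluorescence stack quantification pipeline (median denoising,
    unsharp masking, Richardson-Lucy restoration, skewness-based local
    equalization and adaptive Otsu segmentation). Deterministic synthetic-data
    generators make every component testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    e1071,
    tiff,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), EBImage, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
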