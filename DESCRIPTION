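Package: groatac
Title: Enhancer Calling from Nascent Transcription and Single-Cell Chromatin QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regulatory-genomics toolkit for studying drug-induced chromatin
    and transcription dynamics in leukemia cell models. Calls active enhancers
    from strand-specific nascent transcription (GRO-seq-like coverage) using
    bidirectional eRNA signal with a ten-fold strand-balance rule and
    histone/accessibility evidence filters; detects nucleosome-free dips inside
    broad histone peaks; tests differential nascent activity with a
    negative-binomial quasi-likelihood F-test and an any-change likelihood
    ratio test under median-of-ratios (RLE) normalization; computes per-cell
    scATAC fragment QC including the mononucleosome/nucleosome-free
    "nucleosome signal" and TSS enrichment; scores per-cell transcription
    factor motif activity as background-calibrated deviations; and aggregates
    chromatin-state-specific enhancer signal into binned matrices and average
    profiles. A seeded synthetic-data generator with planted ground truth
    drives end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    edgeR,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
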