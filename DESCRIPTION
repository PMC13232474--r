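Package: chromsig
Title: Chromatin-Derived Subtype Signatures and Tumor Microenvironment
    Analytics for Bladder Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives chromatin-derived subtype signatures (CDS) for
    high-grade T1 bladder cancer by integrating differential H3K27ac
    peak activity with differential gene expression, scores bulk samples
    and single cells against those signatures, and classifies tumors
    into luminal-like inflammatory (LLI), basal-like (BL) and
    micropapillary (MP) states. Also provides a negative-binomial
    differential test with library-size normalization, PERMANOVA cluster
    validation, copy-number inference from off-target scATAC-seq
    fragments with GC-matched background correction, an IHC image
    pipeline (moment-preserving thresholding, stain filtering,
    distance-to-vessel measurement, H-scores), spatial co-occurrence
    curves, survival and association statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    survival,
    png,
    EBImage,
    withr,
    fgsea,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
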