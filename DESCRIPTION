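Package: snapspec
Title: Specificity Analysis of GRHL2 SNAP DNA-Binding Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-density genomic SNAP
    (Specificity and Affinity for Protein) DNA-binding microarrays
    interrogating the Grainyhead-like 2 (GRHL2) transcription factor.
    Provides probe-library design (genomic tiling, mismatch permutation,
    dimer spacing and hairpin controls), replicate intensity
    normalization (global scaling, quantile normalization, median
    collapse), consensus/mismatch motif scanning, flanking-base
    quartile-enrichment analysis, Sequence Specificity Landscape
    construction, a DNA torsional-elasticity helical-phasing model with
    nonlinear least-squares fitting, direct versus indirect genomic
    occupancy classification, and a synthetic array simulator with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    limma,
    tibble,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
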