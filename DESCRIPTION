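Package: epipanel
Title: Gene-Centric Mapping and Pattern Search for Epigenomic Peak Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps ChIP-seq peak calls (BED, broadPeak, narrowPeak) and
    expression tables onto user-selected genes in TSS-relative,
    strand-corrected coordinates, then searches for user-defined epigenetic
    patterns -- such as bivalent promoters or exon-proximal enrichment --
    through a chainable filter algebra. Provides average feature profiles
    (TSS-anchored and gene-body-scaled), feature histograms, expression
    scatter data, gene tables, self-contained JSON session serialization,
    SVG panel export, a deterministic synthetic-data generator with
    plantable patterns, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
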