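Package: ecrap1
Title: Composite EcR-AP-1 Regulatory Element Screening with Synthetic
    Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens candidate transcription-factor binding regions for
    composite regulatory elements defined by degenerate IUPAC motif
    content (at least four AP-1 consensus sites, TGANTCA, and no
    ecdysone-response element), classifies each motif occurrence by its
    overlap with ChIP-seq peak sets, computes gene-context statistics
    (region-to-gene assignment, gene-size comparisons, motif density),
    and quantifies fluorescence in situ hybridization and proximity
    ligation assay images (thresholded pixel fractions inside a
    hand-drawn ROI, fixed-size strip mean gray values, and
    nuclear/cytoplasmic classification of punctate signals). A
    synthetic-data generator plants motifs, regions, peaks, and image
    signals with known ground truth so every pipeline stage is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    knitr,
    pracma,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
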