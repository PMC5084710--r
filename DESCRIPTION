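Package: apexkit
Title: Quantitative Analysis of Oriented Cell Division, Clonal Growth and
    Regulatory Binding in the Shoot Apex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying early stem development from single
    time-point data. Detects recently formed cell walls and their 3D
    orientation in segmented confocal volumes of the shoot apical meristem
    (weakest-wall-signal calling, best-fitting-plane geometry, angles to the
    stem axis and radial directions), assigns walls to meristem zones and
    compares orientation distributions between zones and genotypes, aligns
    and measures clonally marked sectors across apices, and performs
    replicate-consensus ChIP-seq peak selection with strand-aware gene
    attribution and Monte Carlo positional enrichment. Seeded synthetic-data
    generators produce every input with known ground truth so the full
    toolkit is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    tiff,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
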