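Package: ecadscreen
Title: High-Content siRNA Screen Analysis of Membrane-Associated E-Cadherin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide high-content siRNA screens
    that quantify membrane-associated E-cadherin in colorectal cancer
    cells. Implements image-based Ecad scoring (nuclei segmentation,
    ring-expanded cell masks, fibre detection, field-acquisition rules),
    per-plate fold-to-mock normalization with inter-plate robust Z-scores,
    cell-viability binning and pro-survival/anti-proliferative
    classification, miR-200 family seed-sequence off-target exclusion, and
    the 2-of-4 duplex deconvolution validation rule, together with a
    ground-truth synthetic screen generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
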