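Package: ddxpscan
Title: Detection, Typing, and Simulation of Bacterial DDxP Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates the repeat architecture of bacterial DDxP proteins:
    scans protein sequences for degenerate motifs (terminal Asp-Asp-x-Pro
    tetrapeptides, DGDGD Asp-rich motifs, RTX nonapeptides), segments
    proteins into an N region, an array of DDxP repeat modules, and a C
    region, clusters modules into repeat types by pairwise identity, and
    detects the 18-bp target site duplications that flank module-encoding
    DNA. A growth-by-insertion simulator generates synthetic coding
    sequences with logged insertion, amplification, and mutation events so
    scanner output can be validated against known ground truth. Ships a
    machine-readable catalog of 85 published DDxP repeat modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
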