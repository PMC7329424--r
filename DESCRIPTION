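Package: dropsketch
Title: Minhash-Sketch Gene-Cell Count Matrices from Droplet Single-Cell RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes gene-cell molecule count matrices from droplet-based
    single-cell RNA-seq reads (10x Chromium v2 layout) without alignment.
    A reference transcriptome is indexed as a multi-value hash table of
    windowed minhash sketches; reads are classified by accumulating sketch
    feature hits over consecutive reference windows, cell barcodes are
    whitelisted by a sorted prefix-sum rule with edit-distance-one rescue,
    and PCR duplicates are collapsed per cell and gene with the directional
    UMI method. Includes a synthetic read simulator with known ground truth
    and writers for sparse coordinate and MatrixMarket output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    methods,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
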