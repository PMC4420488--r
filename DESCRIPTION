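Package: ligbias
Title: Quantify and Reduce Adaptor-Ligation Bias in Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ligation bias in small RNA sequencing
    library construction against defined reference pools. Reads are
    adaptor-trimmed, annotated by exact match and normalized so that an
    unbiased equimolar pool has a normalized read value of one per
    sequence. Deviations are explained through RNA secondary structure of
    the inserts and joint minimum-free-energy cofold structures of
    insert-adaptor pairs, classified into sixteen ligation-junction
    categories. Positional nucleotide enrichment for randomized-region
    adaptor libraries, bias summary metrics, adaptor design helpers
    (complementary-region and randomized-region adaptors, per-target
    designed adaptors), and a synthetic-data generator with a planted
    structure-driven ligation-efficiency model are included. Pair folding
    uses ViennaRNA's RNAcofold when available; a self-contained dynamic
    programming backend with a simple pair-energy model is provided for
    dependency-free runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
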