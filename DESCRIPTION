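Package: seqlev
Title: Sequence-Levenshtein Error-Correcting DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and decoding of error-correcting DNA barcodes that remain
    correctable when the barcode is embedded at the start of a longer
    sequencing read. Implements the Sequence-Levenshtein distance (an edit
    distance with a free final truncation/elongation step), chemical
    candidate filters (GC content, homopolymer runs, self reverse
    complementarity), greedy-closure evolutionary generation of barcode sets
    with a guaranteed pairwise minimum distance under Hamming, Levenshtein or
    Sequence-Levenshtein metrics, indel-aware decoding that recovers the
    post-mutation word boundary, FASTQ demultiplexing, and mutation
    simulations comparing the failure rates of the different code families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    Biostrings,
    methods,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
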