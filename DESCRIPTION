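Package: longamp
Title: Long-Read rDNA Amplicon Barcoding Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for DNA barcoding with long dual-indexed Nanopore
    amplicons: demultiplexing of noisy long reads by bounded edit-distance
    search of 15-bp indexes and degenerate primers, read quality/length
    filtering, coverage-subsampled consensus calling with iterative
    majority-vote polishing, barcode-gap and Mantel distance statistics,
    metabarcoding fold-change metrics, a dual-index set designer, and a
    Nanopore-like amplicon read simulator with per-read ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
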