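Package: rmapalign
Title: Seed-and-Extend Alignment of Error-Prone Genomic Maps to Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Glocal and overlap alignment of error-prone genomic (optical
    restriction) maps to in-silico sequence maps. Implements a sorted index of
    continuous-valued composite seeds that tolerates one cut error per seed,
    banded dynamic programming extension with a cut-error plus chi-square
    score, and a technology-agnostic statistical evaluation of alignment
    significance and uniqueness based on Z-scores of the candidate population,
    the Wilson-Hilferty transform and false-discovery-rate control. Includes
    in-silico digestion of FASTA sequences, a configurable error-process
    simulator with truth logs, a sliding-window overlap aligner for scaffold
    extension, and evaluation utilities for sensitivity and precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
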