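Package: mirtap
Title: Small RNA Tag Analysis: miRNA Discovery, Differential Expression
    and Target Prediction for Two-Library Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a two-library
    (control vs treatment) plant small RNA sequencing analysis: adapter
    trimming and tag collapsing, genome mapping and annotation-category
    accounting, known-miRNA matching, novel miRNA hairpin discovery under
    six explicit structural qualifications, TPM normalization, the
    Audic-Claverie exact test with a five-way regulation classification,
    plant miRNA target-site scoring, and stem-loop qPCR concordance.
    Includes a ground-truth synthetic data generator so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
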