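Package: oriforge
Title: Replication Origin Prediction and Artificial Origin Design from
    Z-Curve Encoded DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts human DNA replication origins (ORIs) of arbitrary
    length by combining phase-specific Z-curve k-mer encoding with a
    self-attention convolutional neural classifier, and designs artificial
    origin sequences with a genetic algorithm that uses the trained
    classifier as its fitness function. Includes stratified k-fold
    cross-validation with ACC/MCC/AUC reporting, GC-content and
    cosine-similarity analyses of encoded sequence sets, a synthetic
    labelled-sequence generator for download-free benchmarking, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
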