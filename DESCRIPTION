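Package: pathcell
Title: Tumor Versus Normal Cell Discrimination from Pathway Activity in
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates tumor cells from normal cells in single-cell
    RNA-seq data by pooling sparse per-gene counts into per-cell gene-set
    (pathway) activity scores, selecting discriminative pathways with
    Wilcoxon rank-sum tests, and classifying cells with a small fully
    connected neural network trained on binary cross-entropy. Includes
    permutation-based pathway importance, dropout and pathway-inactivation
    robustness simulations, a negative-binomial synthetic data generator
    with planted pathway effects, and readers and writers for 10x-style
    MatrixMarket directories, GMT gene-set files, and dense count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
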