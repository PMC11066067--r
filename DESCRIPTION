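Package: dtlchron
Title: Dated Gene-Tree/Species-Tree Reconciliation and Gene-Family Chronologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Times the origin and spread of gene families on a time-calibrated
    species tree. Implements most-parsimonious dated duplication-transfer-loss
    (DTL) reconciliation with transfers restricted to contemporaneous lineages
    and an unsampled-lineage ("transfer to the dead") channel, amalgamation over
    conditional clade tables built from Bayesian gene-tree samples, extraction of
    dated event chronologies and first-appearance (origin lower bound) estimates
    binned into geological periods, homolog screening by bit-score propagation
    and monophyletic-clade selection, and regression of metagenomic gene
    abundances against environmental phosphate concentrations. A forward
    simulator of gene-family evolution on dated trees provides ground-truth
    event histories so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
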