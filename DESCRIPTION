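Package: dysmir
Title: Dysregulated miRNA-Target Network Analysis with Permutation-Tested
    Correlation Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds dysregulated miRNA-mRNA networks from paired
    tumor/normal expression by scoring condition-dependent rewiring of
    miRNA-target rank correlations against a label-permutation null,
    classifies risk miRNAs from five network and expression features with
    a genetic-algorithm-tuned support vector machine, and runs downstream
    hypergeometric overlap, enrichment, median-split survival,
    immune-infiltration and drug-response association screens. Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
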