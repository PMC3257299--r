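Package: hairnet
Title: Root Epidermis Regulatory Networks from Knockout Perturbation
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the gene regulatory network controlling root
    epidermal cell differentiation from panels of knockout-mutant
    transcriptomes. Implements significance analysis of microarrays (SAM)
    with permutation-based false discovery rate q-values, the two-stage
    core-gene screen (q-value primary screen plus a six-comparison
    fold-change filter), intervention-aware Bayesian network structure
    learning with a BDeu score, greedy and simulated-annealing search over
    directed acyclic graphs, consensus-edge extraction across the
    top-scoring structures, developmental-zone assignment from longitudinal
    root-section profiles, and regulatory-cluster assembly from perturbation
    signatures. A synthetic-data generator simulates the full experimental
    design (multi-site knockout lines, hormone-transfer rescue, phenotype
    characters, section profiles) with known ground truth, so the whole
    pipeline is testable end to end without external data.
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
    igraph,
    methods,
    purrr,
    Rcpp,
    readr,
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
    withr,
    xml2
Config/testthat/edition: 3
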