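Package: tromics
Title: Integrative Trans-Omics Network Analysis for Two-Group Phenotype Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-gene association evidence from multiple omics
    layers (expression, promoter methylation, miRNA expression and
    methylation) for a two-group phenotype contrast using a half-normal
    combined score with permutation standardization, performs signaling
    pathway impact analysis combining over-representation and
    topology-based perturbation evidence, discovers disease modules on a
    weighted interactome by solving the prize-collecting Steiner tree
    problem with calibrated prize weighting, and attaches miRNAs to the
    module through expression anti-correlation and target screening,
    classifying each module gene into one of four regulation patterns.
    Ships a fully synthetic ground-truth data generator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
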