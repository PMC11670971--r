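Package: bocc
Title: Clustering and Classifying Time-Versioned Gene-Phenotype Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hybrid gene-phenotype knowledge networks from STRING-style
    protein links, the Human Phenotype Ontology, and gene-to-phenotype
    annotations; clusters yearly network snapshots with an ensemble of
    community-detection algorithms capped by Paris hierarchical
    sub-clustering; scores each cluster by how many of the following year's
    gene-to-phenotype edges it "rediscovers" against a snowball-sampling
    empirical null; trains dropout-regularised gradient-boosted models that
    predict which clusters are enriched for latent gene-phenotype
    connections from nine biological and topological features; and generates
    per-patient gene-phenotype hypotheses with a term-shuffle permutation
    null. Ships a seeded synthetic-network generator so the whole pipeline
    is testable at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
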