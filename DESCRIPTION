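Package: targetnet
Title: Network Context of GWAS Genes and Drug Targets, with
    Repurposing Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how often genome-wide association study (GWAS)
    reported genes coincide with approved drug targets for the same
    disease, against a random expected-overlap null model; contrasts the
    two gene classes on non-synonymous SNP density, longest transcript
    length and dN/dS; measures their proximity on an undirected protein
    functional-interaction network (shortest distances, neighbor
    enrichment, degree); and trains a cost-sensitive random forest on
    network features (GWAS first/second-neighbor counts, degree, and
    Jaccard common-neighbor scores) to rank existing drug targets as
    repurposing candidates. Includes seeded generators for synthetic
    networks, disease gene sets, variant tables and gene annotations so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    Matrix,
    vcfR,
    randomForest,
    pROC,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
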