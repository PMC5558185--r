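Package: pdrank
Title: Phenotype-Driven Ranking of Candidate Diseases, Genes and Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks candidate diseases (and their associated genes
    and variants) for a patient by traversing a phenotype-disease-gene
    knowledge network with a specificity- and path-length-weighted heuristic.
    Provides loaders and validators for node/edge-table networks and OBO
    hierarchies, a synonym lexicon mapper for free-text phenotype terms and
    HPO-style identifiers, a rare-disease variant filter cascade (call
    quality, population allele frequency, predicted deleteriousness, trio
    de novo), the constrained shortest-path scoring algorithm itself, a
    ranked disease-gene-variant result table, and a seeded synthetic-network
    and planted-case simulator for benchmarking recovery of causal genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
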