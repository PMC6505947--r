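Package: penguinproc
Title: Community Assembly Process Partitioning for Penguin Faecal Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for downstream 16S OTU-table analytics in a
    two-species by two-stage (feeding/moulting) penguin gut microbiome design:
    singleton removal, rarefaction, Hellinger transform, Bray-Curtis
    dissimilarity, Shannon diversity, taxonomic aggregation, non-metric
    multidimensional scaling with group ellipses, two-factor PERMANOVA with
    interaction, Welch t-tests with Benjamini-Hochberg correction, and
    phylogenetic null-model partitioning of community assembly processes via
    the beta nearest taxon index (betaNTI) and the Bray-Curtis Raup-Crick
    metric (RC-bray).  Includes seeded simulators for phylogenies, traits and
    community tables under neutral, selective and dispersal-limited assembly
    regimes so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
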