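Package: endocore
Title: Diversity, Co-Occurrence Networks and Core-Microbiome Analysis for
    Plant Endophyte Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing succession of plant endophytic fungal
    communities from genus- or OTU-level abundance tables: depth
    normalization by rarefaction, alpha diversity (Chao1, Shannon evenness,
    finite-sample Simpson dominance, rooted Faith phylogenetic diversity),
    beta diversity (Bray-Curtis and normalized weighted UniFrac distances,
    UPGMA clustering, principal coordinates analysis, ANOSIM permutation
    tests), Spearman co-occurrence network construction with
    centrality-threshold hub classification, a combined membership-plus-hub
    core-microbiome definition, and Spearman association of core taxa with
    compound (quinolizidine alkaloid) content.  Includes a seeded synthetic
    community generator with planted correlation cliques and planted
    taxon-compound relationships so the whole workflow is testable without
    sequencing data, and a single-seed end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
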