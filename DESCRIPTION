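Package: halimicro
Title: Oral Microbiome Analysis of Childhood Halitosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tongue-coating and saliva microbial
    communities in children with and without halitosis. Implements
    rarefaction, Chao1 richness, weighted UniFrac with permutational AMOVA,
    Wilcoxon/Fisher differential OTU screening with PCA, permutation-null
    Pearson co-occurrence networks with hub and edge-class analysis, tiered
    core-microbiome classification, an exact two-library differential gene
    test with hypergeometric KO enrichment, and a hydrogen-sulphide pathway
    gene-family report. Includes a seeded synthetic-data generator that
    plants differential OTUs, correlated OTU pairs and gene-family fold
    changes with a recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    xml2
Config/testthat/edition: 3
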