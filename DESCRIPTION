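Package: parasitome
Title: Host-Parasite Microbiome Congruence and Co-Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired host-parasite bacterial community surveys:
    prevalence and abundance filtering of amplicon sequence variant (ASV)
    tables, alpha diversity (richness, inverse Simpson, evenness, Faith's
    phylogenetic diversity), weighted UniFrac distances with principal
    coordinates analysis, symmetric Procrustes congruence tests with a
    leave-one-out clade-attribution statistic (delta-t), compositional
    co-association network inference (SparCC-style log-ratio correlations
    and neighborhood-selection with stability selection), network summary
    statistics, and bootstrap Kolmogorov-Smirnov comparison of node
    centrality distributions. Includes a synthetic paired-community
    generator with tunable host-parasite congruence strength, planted
    driver clades and plantable co-association graphs, so every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    igraph,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phyloseq,
    withr
Config/testthat/edition: 3
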