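Package: cliqueModules
Title: Regulatory Module Identification in Protein-Protein Interaction
    Networks by Randomized Clique Enumeration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Approximates the community structure of a protein-protein
    interaction network (PPIN) by iterative, randomized enumeration of
    cliques grown from random seed proteins. Each enumerated clique is
    tested for enrichment with differentially expressed genes (DEGs)
    using a one-sided Fisher exact test embedded in a permutation scheme
    against gene sets sampled from the platform background. The union of
    significantly enriched cliques forms a phenotype-specific regulatory
    module, which is partitioned into sub-modules by edge-betweenness
    community detection and whose reproducibility is quantified by
    bootstrap resampling of enumeration iterations. Includes readers and
    writers for STRING-style edge lists, SIF, GraphML and plain gene
    lists, and a synthetic-data generator with planted cliques and
    planted DEG enrichment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
biocViews: Network, GraphAndNetwork, NetworkInference, GeneExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
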