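Package: cranionet
Title: Anatomical Network Analysis of Skull Bone Fusion and Its Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anatomical network analysis (AnNA) of skulls scored as
    bone-contact graphs. Reads symmetric 0/1 bone-adjacency matrices, models
    ontogenetic bone fusion, computes the standard network descriptors
    (density, clustering, path length, degree heterogeneity), detects
    connectivity modules by hierarchical clustering of the generalized
    topological overlap matrix with Newman-Q optimal dendrogram cuts and
    Wilcoxon-based S-module significance, builds a Gower/PCoA morphospace,
    and runs the comparative battery: Mann-Whitney and Kolmogorov-Smirnov
    group tests, ordinary least-squares allometry with ANCOVA slope tests,
    PERMANOVA, phylogenetic flexible discriminant analysis with Pagel's
    lambda, and Brownian-motion ancestral state reconstruction with
    juvenile-substitution heterochrony tests. A synthetic-data module
    generates bilaterally symmetric skull networks, fusion schedules and
    trait-bearing clock trees so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    MASS,
    vegan,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phytools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
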