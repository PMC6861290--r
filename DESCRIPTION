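Package: rhizonet
Title: Cross-Kingdom Co-Occurrence Network Analysis of Root Microbiome
    Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-denoising stages of paired bacterial and
    fungal amplicon surveys of plant root microbiomes: sequence-variant
    table filtering, taxonomy fill-down and agglomeration, rarefaction,
    community distances (Bray-Curtis, Jaccard, Jensen-Shannon divergence),
    iterative rarefied richness, first-principles multivariate inference
    (PERMANOVA, Mantel, non-metric multidimensional scaling), and
    per-treatment-group Spearman co-occurrence matrices with tiered
    interaction counts and cross-kingdom network construction. Includes a
    seeded generator for synthetic paired-kingdom experiments with planted
    correlation structure and treatment-dependent composition shifts, and
    an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
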