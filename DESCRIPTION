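Package: striamic
Title: Stress-by-Exercise Single-Nucleus RNA-Seq Analysis of Striatal Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a single-nucleus
    RNA-seq analysis of striatal microglia under acute stress and voluntary
    exercise. Provides barcode-level quality-control filters, Gamma-Poisson
    Pearson-residual normalisation, PCA and shared-nearest-neighbour graph
    clustering with resolution selection by a k-minimum-spanning-tree
    standardized within-cluster edge-count statistic, a transcriptional
    diversity (maturity) score, negative-binomial mixed-model differential
    expression with library-size offsets and Storey q-values, per-nucleus
    gene-set state scores with linear mixed-model comparisons, composition
    and goodness-of-fit tests, over-representation and preranked gene-set
    enrichment, and bootstrap causal mediation. A synthetic-data module
    emulates the study design (4 groups x 6 individuals, negative-binomial
    counts with per-gene dispersion, individual random intercepts, planted
    clusters, a maturity gradient, treatment effects and QC violators) so
    every stage is exercised without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    lme4,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr,
    cluster
Config/testthat/edition: 3
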