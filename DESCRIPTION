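Package: graphburden
Title: Patient-Specific Graph Benchmarks for Genotype-to-Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Graphburden", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds patient-specific graphs from per-gene missense variant
    burdens laid over a disease gene interaction subnetwork, and benchmarks a
    graph neural network classifier against tabular machine-learning baselines,
    a single-gene (APOE-style) logistic baseline, and degree-preserving
    randomized-network null models. Includes network extraction (induced
    subgraph, largest connected component, graph statistics), VCF-based
    missense burden counting, amyloid-PET / diagnosis / case-control labeling
    rules, a synthetic cohort generator with an optional edge-aligned epistatic
    signal, stratified nested cross-validation, and the fold-wise statistical
    testing protocol with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
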