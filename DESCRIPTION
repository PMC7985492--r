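Package: npclust
Title: Cluster Discovery and Network Analysis for Preschool Neuropsychological Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a 52-test neuropsychological battery administered to
    preschoolers (30-71 months): score normalization and age binning, permutation-surrogate
    significance for test-test correlation matrices, k-means cluster discovery with
    Calinski-Harabasz and Davies-Bouldin model selection and nested sub-clustering,
    developmental trajectory regression with size-matched subsampling, betweenness-centrality
    networks of the test battery with centrality-ranked k-nearest-neighbour classification,
    and permutation-validated multivariable regression on domestic and educational predictors.
    Includes a synthetic cohort generator that emulates the statistical structure of the
    study design, so every stage is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
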