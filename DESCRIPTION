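Package: immunet
Title: Cross-Dataset Co-Expression Meta-Analysis of Immune Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-analysis of multi-experiment expression compendia for
    immune-response gene discovery. Builds co-expression networks from
    within-group (per-dataset, sample-size weighted) Pearson correlations so
    that between-dataset batch differences do not create edges, clusters the
    thresholded graph with a from-scratch Markov Cluster (MCL) algorithm,
    and characterises clusters by term enrichment (Fisher/EASE exact tests
    with Benjamini-Hochberg FDR), centered expression profiles and
    permutation-based per-dataset activation calls. Includes array-level
    quality control with a fail-more-than-one-metric removal rule, a seeded
    synthetic compendium generator with planted response clusters for
    end-to-end validation, and comparative-immunome utilities: gene-family
    expansion/contraction classification against a reference species,
    four-species ortholog Venn-region queries, assembly-artifact duplication
    classification and annotation-summary aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph
Config/testthat/edition: 3
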