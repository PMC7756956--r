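Package: plateletcc
Title: Cross-Species Comparison of the Platelet Central Signalling Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the central activating signalling cascade of
    blood platelets between human and mouse. Provides ortholog-aware merging of
    per-species protein-protein interaction networks into a combined network,
    Bayesian interolog confidence scoring, median-log2 normalisation of RNA-seq
    (RPKM) and semi-quantitative proteome abundance tables, a transcriptome-
    proteome cross-species concordance score and four-class classification
    (matched, compatible, opposite, unclear), breadth-first neighbour-degree
    annotation around a central-cascade seed set, expression-difference
    filtering, Cytoscape-ready attribute assignment, GraphML/SIF export, and a
    synthetic two-species data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
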