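Package: mirsig
Title: miRNA Drug-Resistance Signature Profiling and Target Integration
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "pipelines@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for microarray-based miRNA drug-resistance
    profiling in cell-line panels. Provides the RMA core (quantile
    normalization and median-polish summarization) for log2 intensity
    matrices, per-contrast differential expression with an empirical-Bayes
    moderated t-test and Benjamini-Hochberg false-discovery-rate control,
    signed fold-change calling, a two-tier resistance-signature selection
    rule (consistent change in both lines resistant to the same drug, or a
    strong change in a single line), and miRNA-to-target integration that
    aggregates target databases, retains inversely regulated miRNA-gene
    pairs, subsets by Gene Ontology keywords, and exports
    Cytoscape-importable networks. A synthetic-data generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    igraph,
    optparse
Config/testthat/edition: 3
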