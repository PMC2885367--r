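Package: tissuecons
Title: Cross-Platform Comparison and Consolidation of Tissue-Specific
    Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing and integrating tissue expression
    compendia measured on different microarray or sequencing platforms.
    Implements tissue-specificity scoring with the preferential
    expression measure (PEM) and the MAX uniqueness score, permutation
    based empirical false discovery rates, correlation-of-correlations
    similarity between datasets with randomized baselines, sample-size
    calibration of FDR thresholds, mean-rank consolidation of gene
    rankings with leave-one-out cross-validation, and enrichment
    profiling over informative ontology categories.  A synthetic
    multi-platform compendium generator with planted tissue-specific
    genes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
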