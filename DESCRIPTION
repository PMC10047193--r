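Package: dephub
Title: Differential Proteome Analysis with Effect-Size DEP Calling and
    Topological Hub Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-quantification analysis of label-free DIA proteomics
    experiments comparing two groups of replicates. Implements
    missing-value filtering, group-exclusive protein detection, per-sample
    mean imputation, Welch t-tests with Cohen's effect-size based calling
    of differentially expressed proteins (DEPs), parametric log
    fold-change outlier detection, sample-level clustering and PCA quality
    control, Monte-Carlo chi-squared association of DEP direction with
    ontology categories (with Pearson-residual localization), consensus
    hub-protein identification on scored protein-protein interaction
    networks via Degree, maximum neighborhood component (MNC) and maximal
    clique centrality (MCC), and confidence-score filtering of
    gene-disease association tables. Includes a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
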