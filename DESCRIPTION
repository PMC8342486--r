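Package: epibit
Title: Exhaustive Higher-Order Epistasis Search with a Bitwise Counting Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive detection of epistatic interactions among up to four
    bi-allelic SNVs in case/control cohorts. Genotypes are packed two bits per
    sample so the 3^m x 2 genotype-combination contingency table of any m-SNV
    tuple is built by bitwise shift/OR and a byte histogram; a Gini-purity
    combined association power (beta) and an interaction effect size (alpha)
    are computed per tuple, with permutation-based empirical and fitted-tail
    p-values and Bonferroni correction. Includes a penetrance-model simulator
    for detection-power studies and Cytoscape-ready interaction-graph export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods, SummarizedExperiment
Imports:
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    VariantAnnotation,
    data.table,
    igraph,
    jsonlite,
    fitdistrplus
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
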