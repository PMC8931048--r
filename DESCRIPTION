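Package: epicmml
Title: Integrative Epigenomic Analysis of ASXL1-Mutant CMML
Version: 0.1.0
Authors@R: person("CMML", "Epigenomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tested, reusable pipeline for the integrative epigenomics of
    chronic myelomonocytic leukemia (CMML) stratified by ASXL1 mutation
    status: multi-replicate consensus peak calling with weak/stringent
    double thresholds and Fisher evidence combination, chromatin-state
    segmentation with a product-Bernoulli hidden Markov model and genotype
    contrasts over promoter windows, rank-based state-expression
    association (Mann-Whitney, Cuzick trend), gene-body
    (hydroxy)methylation dosage and threshold models, genotype-specific
    distal enhancer discovery with TAD-constrained basal-plus-extension
    target assignment, a multivariable log-linear expression model with
    e^beta - 1 effects and LMG relative-importance decomposition, and
    entropy-based single-cell diversity and specialization statistics.
    Ships a seeded synthetic-study generator with planted ground truth so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
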