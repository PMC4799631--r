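Package: genwin
Title: Generation-Windowed Genomic Prediction for Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the number of ancestral training generations
    affects the accuracy of genomic prediction in closed breeding populations
    such as layer-chicken lines. Provides a multi-generation population
    simulator with linkage disequilibrium, truncation selection and
    hatch-within-generation fixed effects; pedigree algebra (numerator
    relationship matrix, Henderson's rules for its sparse inverse, inbreeding,
    generation truncation); single-trait animal-model REML and mixed-model
    equation BLUP; BayesB and BayesC0 whole-genome regression samplers with
    marker-based heritability and Heidelberger-Welch convergence diagnostics;
    SNP quality control; a training/validation sweep over generation windows
    and training-set size/composition scenarios; and a quadratic-regression
    estimator of the optimal number of training generations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    yaml
Config/testthat/edition: 3
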