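Package: metimp
Title: Missing-Value Imputation, Amputation Simulation and Benchmarking
    for Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for handling missing values in metabolomics feature
    tables (samples in rows, metabolite intensities in columns). Provides
    a validated intensity-matrix data model with delimited-text input and
    output and configurable missing-value encodings (NA tokens, zeros,
    ones); a ground-truthed amputation simulator covering MCAR, MAR,
    limit-of-detection MNAR and their mixtures; eleven native imputation
    methods (constant strategies, random-range baseline, K-nearest
    neighbours, iterative low-rank SVD completion, regularized iterative
    PCA, missForest-style random-forest imputation and quantile-based
    left-censored imputation) behind one uniform contract that never
    alters observed cells; an NRMSE benchmark harness with per-attempt
    wall-clock timeouts, retries and stability accounting; and a
    pattern-aware method recommender.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    ranger,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
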