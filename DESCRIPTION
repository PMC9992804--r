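Package: spidnmf
Title: Stage-Prior-Informed Joint Non-Negative Matrix Factorization for
    Multi-Omics and Histopathology Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint non-negative matrix factorization of sample-aligned
    multi-view data (histopathology image features, miRNA and mRNA
    expression) sharing a single sample-basis matrix, with optional
    orthogonality and sparsity penalties, cross-modal absolute-Pearson
    coupling priors, and a clinical-stage sample-graph Laplacian penalty
    that pulls same-stage samples together in factor space. Includes
    NNDSVD initialization, multiplicative update rules, hyperparameter
    grid search with early stopping, co-expression module extraction and
    scoring, per-nucleus to patient-level aggregation of whole-slide
    image features, survival-based biomarker screening with linear risk
    scoring, and a synthetic multi-view data generator with planted
    factors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
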