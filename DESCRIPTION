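Package: oddoneout
Title: Sparse Positive Similarity Embeddings from Triplet Odd-One-Out
    Judgments and Multimodal Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modeling human similarity judgments collected with
    the triplet odd-one-out task and for linking the resulting embeddings
    to neuroimaging measurements.  Implements sparse positive similarity
    embedding (SPoSE) estimation by projected Adam with an L1 penalty,
    cross-validated regularization selection, and reproducibility-based
    model selection across random restarts; explainable-variance noise
    ceilings for repeated neuroimaging measurements and choice-consistency
    ceilings for repeated behavioral triplets; exponential-decay
    extrapolation of embedding dimensionality versus dataset size with
    bootstrap confidence intervals; choice-probability similarity matrices,
    representational similarity analysis with object-level bootstrap, and a
    multi-dataset improvement test; and time-resolved regression-based
    MEG-to-fMRI fusion with leave-one-session-out cross-validation.  A
    synthetic-data module generates every input with known ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
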