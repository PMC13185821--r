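Package: traitfactor
Title: Stability-Driven Non-Negative Decomposition of Personality Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orthogonal projective non-negative matrix factorization (OPNMF) of
    Likert-scale personality inventories, with a cross-validated stability and
    generalizability framework for choosing the number of factors (adjusted Rand
    index, variation of information, concordance of loading patterns, increased
    reconstruction error, item variability), subgroup generalizability analysis
    with permutation-null adjustment, and a two-dimensional trait space with
    directional thresholded partial-least-squares prediction, permutation and
    bootstrap inference. Includes a synthetic Likert-response and phenotype
    generator with planted factor structure so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics,
    withr
Config/testthat/edition: 3
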