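Package: episnp
Title: Interacting-SNP Selection for Case-Control Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies groups of interacting single nucleotide polymorphisms
    (SNPs) that jointly predict case-control status. A gradient tree boosting
    model ranks SNPs by split gain, and an adaptive iterative top/bottom-list
    search re-ranks and swaps candidates to surface SNP-SNP interaction
    patterns; the selected group feeds a linear support vector machine
    back-end. Includes a polygenic risk score (PRS) baseline, penalized
    logistic-regression selection (lasso, ridge, elastic net), precision-recall
    and average-precision metrics, repeated stratified nested cross-validation,
    an estrogen-receptor subtype classification protocol, and a two-cohort
    synthetic genotype simulator (Balding-Nichols population structure, Markov
    copying linkage disequilibrium, logistic phenotypes with marginal and
    purely epistatic effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
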