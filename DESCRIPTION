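Package: famet
Title: Factor-Analytic Mixed Models for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of plant-breeding multi-environment trials
    (MET). Stage one fits per-trial linear mixed models by REML and reports
    genotype BLUPs, adjusted means, Cullis heritability, experimental
    accuracy and coefficients of variation. Stage two fits joint
    factor-analytic (FA_k) mixed models to the genotype-by-environment table
    of adjusted means, with AIC order selection, percentage of genetic
    variance explained, between-environment genetic correlations and
    prediction of genotype performance in tested and untested environments.
    Stability is assessed by latent regression on varimax-rotated
    environmental loadings, complemented by classical AMMI and GGE
    decompositions, joint variance components and Pearson correlations
    between environmental covariates and factor loadings. A synthetic MET
    generator with factor-analytic genetic covariance, heterogeneous
    residual variances and controlled unbalance supports simulation studies
    and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
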