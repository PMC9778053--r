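Package: embai
Title: Genomic Selection with Polygenic-Background Whitening and EM-BayesA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage genomic selection. Stage one estimates the ratio of
    polygenic to residual variance on the reduced mixed model by restricted
    maximum likelihood and whitens the phenotype, covariates and marker matrix
    with the symmetric inverse square root of the implied covariance. Stage two
    estimates all marker effects jointly by a fast expectation-maximisation
    algorithm for BayesA, giving genomic estimated breeding values (GEBV).
    Includes EM baselines (BayesA without whitening, ridge regression, Gaussian
    maximum likelihood, spike-and-slab BayesC), a Hardy-Weinberg simulator with
    configurable QTN architectures and polygenic background, VanRaden genomic
    relationship matrices, evaluation metrics (MSE, MAE, Pearson r, coefficient
    AUC), and a scenario-grid benchmark driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
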