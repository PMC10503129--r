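Package: momgwas
Title: Bayesian Variable Selection for Non-Gaussian GWAS with Nonlocal Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage Bayesian variable selection for genome-wide association
    studies with binary or count phenotypes. Phenotypes are modelled with
    generalized linear mixed models carrying a kinship random effect and an
    overdispersion random effect, fitted by penalized quasi-likelihood with a
    population-parameters-previously-determined (P3D) spectral approximation.
    A screening step combines per-SNP generalized least squares summaries with
    a Dirac/product-moment (pMOM) nonlocal mixture prior, empirical-Bayes
    hyperparameter estimation, and Bayesian false discovery rate control; a
    model-selection step scores subsets of the screened candidates under a
    multivariate pMOM prior with Monte-Carlo marginal likelihoods, by
    exhaustive enumeration or a genetic algorithm. Includes a frequentist
    single-marker baseline with Bonferroni correction, simulation of
    structured genotypes and GLMM phenotypes, and buffered detection scoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
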