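Package: vada
Title: Variational Deep Alliance Models for Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the Variational Deep Alliance (VaDA) model, a deep generative
    auto-encoder for longitudinal data that couples a Gaussian-mixture latent
    prior with cluster-specific linear marginal models on latent "pure
    outcomes" and a decoder that induces within-subject dependence. Provides
    joint outcome prediction, subject clustering and representation learning,
    trained by stochastic gradient variational Bayes with the
    reparameterization trick. Includes baseline pipelines (VaDE, VAE, Gaussian
    mixture clustering, cluster-specific marginal models solved by generalized
    estimating equations under independence, AR-1 and exchangeable working
    correlations), a synthetic longitudinal benchmark generator, and
    evaluation utilities (MSE, adjusted Rand index, classification error).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    mclust,
    readr,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
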