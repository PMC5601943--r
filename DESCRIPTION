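Package: cgergm
Title: Correlation Generalized Exponential Random Graph Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative statistical modelling of positive-semidefinite
    correlation networks via the correlation Generalized Exponential Random
    Graph Model (cGERGM). A correlation matrix is reparameterized as a vector
    of unconstrained partial correlations, mapped through Beta cumulative
    distribution functions onto a bounded network on which topological
    statistics (two-stars, triads) are modelled by an exponential family with
    geometric down-weighting, while exogenous dyadic covariates (hemisphere
    homophily, inter-region distance) enter through a logit-link Beta
    regression. Provides Metropolis-Hastings simulation of valid correlation
    matrices, Monte-Carlo maximum-likelihood estimation with Wald inference,
    simulation-based goodness-of-fit, conditional edgewise prediction against
    a maximum-entropy null, and a parameter-recovery simulation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
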