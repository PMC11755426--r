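Package: fakenrm
Title: Modeling Faking and Response Styles with the Multidimensional
    Nominal Response Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the multidimensional nominal response model (MNRM) with
    fixed scoring weights for substantive traits, extreme and midscale
    response styles, and an item-specific faking dimension whose weights
    are derived from social-desirability ratings.  Estimation uses
    stochastic-approximation marginal maximum likelihood
    (Metropolis-Hastings Robbins-Monro); maximum a-posteriori person
    scoring, likelihood-ratio/AIC/BIC model comparison, and a Monte Carlo
    engine for parameter-recovery and model-selection studies are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
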