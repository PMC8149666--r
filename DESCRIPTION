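Package: actionpath
Title: Actionable Treatment-Path Planning with a Stochastic Bayesian Surrogate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Plans actionable stepwise intervention paths on tabular health
    data. A predictive model (gradient-boosted trees by default, or any
    user-supplied predictor) is approximated by a stochastic surrogate: a
    hierarchical Bayesian mixture over continuous and discrete explanatory
    variables and the model's predictions, fitted by Markov chain Monte Carlo
    with the number of components selected by the widely applicable Bayesian
    information criterion (WBIC). The intervention-variable space around an
    instance is discretized into a grid graph and a uniform-cost search
    returns the most actionable path - the sequence of single-variable unit
    changes that improves the predicted outcome while traversing states of
    high probability under the surrogate. Includes actionability scoring
    against random shortest baseline paths, guideline-direction comparator
    paths, and a generator for mixture-of-Gaussians benchmark tables with
    discrete columns and missing values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pROC,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
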