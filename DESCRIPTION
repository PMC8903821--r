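Package: bgschema
Title: Basal-Ganglia Schema Selection Models of Rule-Induction Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and scores two classic rule-induction tasks of
    executive function, the Wisconsin Card Sorting Test (WCST) and the
    Brixton Spatial Anticipation Test (BRXT), using a neurocomputational
    model of schema selection in which competing cortico-striato-thalamic
    loops arbitrate between task rules and responses.  Includes Heaton-style
    perseverative and set-loss error scoring for the WCST, the three
    Brixton perseveration taxonomies, reward-prediction-error threshold
    learning and conflict-driven cortical gain adaptation in the model,
    simulated-annealing fits of model parameters to published group
    statistics with z-score and Bayes-factor fit indices, full-range
    parameter grid scans, a nonparametric/Bayesian statistics battery,
    and a synthetic-participant generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
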