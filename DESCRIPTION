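Package: evohis
Title: Evolutionary Hyperparameter Optimization for Clinical Binary Classifiers
Version: 0.1.0
Authors@R: person("evohis", "maintainers", email = "maintainers@evohis.dev", role = c("aut", "cre"))
Description: Hybrid intelligent systems for disease diagnosis on tabular binary
    datasets. Three population metaheuristics (particle swarm optimization,
    gravitational search, firefly algorithm) evolve the hyperparameters of
    support vector machine and multilayer perceptron classifiers to maximize a
    weighted combination of prediction accuracy, specificity and sensitivity
    estimated by stratified 10-fold cross-validation. Includes Weka-style
    supervised instance resampling, a synthetic binary-dataset generator,
    Pareto-front quality metrics (generational distance, spacing), and a
    statistical validation harness (Wilcoxon signed-rank and one-sample t
    tests).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
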