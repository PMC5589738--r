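Package: anfiswoa
Title: Adaptive Neuro-Fuzzy Regression Trained by the Whale Optimization Algorithm
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A five-layer Sugeno adaptive neuro-fuzzy inference system (ANFIS)
    for tabular regression whose Gaussian membership and linear consequent
    parameters are fitted by the whale optimization algorithm (WOA), with
    particle swarm and genetic algorithm baselines behind the same interface.
    Fuzzy c-means clustering selects the rule count and seeds the premise
    parameters. Includes min-max normalization, repeated random-split and
    k-fold cross-validation evaluation with RMSE and average absolute percent
    relative error (AAPRE), a synthetic data generator emulating seasonal
    proximate-composition studies of fish protein hydrolysates, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
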