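Package: mpenull
Title: Null Models for Detecting Emergent Multiple Predator Effects
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to predict prey consumption by multiple predators under the
    assumption of independent predator effects, and to detect emergent multiple
    predator effects (MPEs) as deviations from those predictions. Implements the
    multiplicative risk model, the direct functional-response approach (replicate
    pairing, Rogers random predator fits, bootstrap confidence bands) and the
    population-dynamic approach (prey-depletion ODE with per-predator functional
    responses and Latin-hypercube prediction intervals), together with a stochastic
    predation-trial simulator and a bias-quantification sweep comparing the three
    null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
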