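Package: pyloricnet
Title: Pyloric Pattern Generator Models with Homeostatic Bias Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating three-neuron continuous-time recurrent
    neural network (CTRNN) models of the crustacean pyloric central pattern
    generator, detecting and classifying triphasic burst rhythms, scoring
    them against pyloric ordering and timing criteria, and studying
    activity-dependent homeostatic plasticity (ADHP) acting on neuronal
    biases. Includes a microbial genetic algorithm for evolving pyloric
    circuits and homeostatic regulators, grid scans of the ADHP-accessible
    bias subspace, and a cycle-averaging nullcline framework that predicts
    when local activity regulation can restore the circuit-level property
    of pyloricness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
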