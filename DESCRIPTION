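Package: smcsynth
Title: Parameter Synthesis for Stochastic Biological Models by Bayesian
    Statistical Model Checking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether a stochastic model of a
    biological system satisfies a probabilistic bounded linear temporal
    logic (PBLTL) specification, and for discovering model parameters
    that make it do so.  Provides a bounded-LTL monitor over finite
    simulation traces, a Bayesian sequential statistical model checker
    with a conjugate closed-form Bayes factor (plus a Wald SPRT
    baseline), and a simulated-annealing search over bounded parameter
    spaces that uses the checker's sample count as its fitness signal.
    Ships small parameterized Markov-chain fixtures with exact
    satisfaction-probability oracles and a desk-scale agent-based model
    of the acute inflammatory response to endotoxin as an end-to-end
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
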