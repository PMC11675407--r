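Package: causalfid
Title: Causal Effect Identifiability Under Functional Dependencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether a causal effect Pr(Y|do(x)) is identifiable from
    observational data given a causal diagram with hidden variables, explicit
    positivity constraints, and qualitatively functional variables (variables
    known to be deterministic functions of their parents, without knowing the
    functions).  Implements functional elimination and functional projection of
    causal diagrams, D-separation for graphs with deterministic nodes, latent
    projection onto acyclic directed mixed graphs, the ID algorithm with
    symbolic estimands, and a reduction pipeline that converts functional
    identifiability questions into classical ones.  Ships a fully parameterized
    discrete causal-Bayesian-network oracle that numerically verifies
    identifiability decisions, plus a random-graph experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
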