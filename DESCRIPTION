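Package: conceptmdp
Title: Concept Learning by State-Space Expansion and Reduction in Active
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for discrete-state (POMDP-style) active inference
    agents that acquire conceptual categories by engaging spare hidden-state
    "slots". Provides factorized categorical generative models with
    Dirichlet-parameterized likelihood and initial-state priors, variational
    belief updating with expected free energy (risk, ambiguity, novelty)
    policy evaluation and precision (dopamine) dynamics, experience-dependent
    concentration-parameter learning, Bayesian model reduction over
    initial-state priors for pruning redundant concepts, a built-in
    animal-categorization task (basic and subordinate categories), a scripted
    experiment grid (concept addition, duplication avoidance, granularity
    learning, model recovery, one-shot generalization), and simulated
    neurophysiological readouts (firing rates, local field potentials,
    phasic dopamine).
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
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
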