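Package: wtacircuit
Title: Canonical Winner-Take-All Circuits for Competitive Selection
Version: 0.1.0
Authors@R:
    person("Priya", "Raman", email = "priya.raman@example.org",
           role = c("aut", "cre"))
Description: Firing-rate simulator of a canonical four-layer neural circuit
    for competitive selection among options, with independently toggleable
    motifs: global feedforward inhibition (comparison), donut-like inhibition
    (categorical selection boundaries), reciprocal inhibition of inhibition
    (dynamically flexible boundaries), combinatorial multilobe inhibitory
    codes (selection among all option pairs at minimal metabolic and wiring
    cost), nonlinear multi-source inhibition combination (selection among
    more than two options), and point-to-point recurrent amplifiers with a
    first-to-threshold readout (unitary choice). Includes the exact
    idealized winner-take-all oracle, the standard behavioural assays
    (competitor-strength response profiles, categorization index,
    transition-norm flexibility, multi-option scaling, unitary-choice
    statistics), circuit perturbations that emulate causal experiments, a
    synthetic stimulus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
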