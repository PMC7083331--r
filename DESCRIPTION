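Package: emtkinetics
Title: Multi-State Markov Kinetics of the Epithelial-to-Mesenchymal Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and stochastic tools for modelling the
    epithelial-to-mesenchymal transition (EMT) as an absorbing
    continuous-time Markov chain with hidden microstates. Provides
    Arrhenius energy-barrier rate assignment over chain, parallel-path,
    layered, and stabilized-state topologies; closed-form occupancy and
    first-arrival-time (phase-type Erlang/hypoexponential) solutions with
    numerically stable incomplete-gamma evaluation; a Gillespie
    single-cell simulator; grid-search fitting of hidden-microstate
    counts to population macrostate time courses; and a synthetic
    time-course generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
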