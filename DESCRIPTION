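Package: rosemarkov
Title: Discrete-Time Markov Illness-Death Model of Suicide Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Four-state discrete-time Markov illness-death model of suicide
    dynamics in a closed population with death-replacement. Provides the
    one-year evolution step (with and without replacement of deaths by
    healthy newborns), the closed-form stationary distribution and a power
    iteration solver, analytic sensitivity coefficients of the equilibrium
    suicide count with respect to every annual transition probability,
    first-order projections of intervention effects, a scenario sweep
    comparing population-wide versus high-risk suicide prevention
    strategies (the Rose prevention paradox), a stochastic cohort
    microsimulation of the same dynamics, and re-estimation of the
    transition probabilities from simulated transition tallies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, tools, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
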