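Package: lgrefuge
Title: Leslie-Gower Predator-Prey Dynamics with a Prey Refuge
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for a modified Leslie-Gower predator-prey
    model with a Holling type II functional response and a constant-proportion
    prey refuge. Computes boundary and interior equilibria with their
    existence classification, linearized stability verdicts by eigenvalue
    analysis cross-checked against a sufficient polynomial criterion,
    constructive global-attractivity and permanence certificates built from
    monotone iterative bounding sequences, and numerical trajectories and
    refuge-parameter sweeps via adaptive ODE integration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
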