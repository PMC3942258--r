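Package: cdipatterns
Title: Competition Dynamics and Spatial Patterns of Bacterial Populations
    with Contact-Dependent Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a two-species nonlocal
    Lotka-Volterra competition model of bacterial contact-dependent
    inhibition (CDI). Implements the well-mixed, one-dimensional, and
    two-dimensional discretized dynamics with periodic boundaries, an
    adaptive Runge-Kutta 4(5) integrator with negativity clamping and
    convergence detection, closed-form steady states with linear stability
    and a Lyapunov surface for the well-mixed limit, the zero-diffusion
    two-domain trial steady state and the analytic slow-diffusion
    coexistence condition, initial-condition generators (representative
    two-domain sets, seeded random fields, nested squares), and
    run-length-based classification of localized stripe patterns with
    ensemble statistics and phase-diagram scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
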