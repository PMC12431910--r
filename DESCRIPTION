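Package: replinet
Title: Replicator Dynamics on Networks with Linear and Delayed Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates evolutionary game dynamics on networks of habitats.
    Each node evolves species frequencies on the probability simplex under the
    replicator equation for a local payoff matrix, and nodes exchange density
    through a transport term: either linear diffusive coupling with a transfer
    velocity, or a delayed, survival-weighted exchange that accounts for travel
    time along edges. Provides equilibrium classification (fixed points, Nash,
    evolutionarily stable states), stability bounds in terms of the network's
    maximum degree, a fourth-order two-stage Gauss-Legendre implicit Runge-Kutta
    integrator in predictor-corrector form with explicit and implicit Euler
    baselines, cubic Hermite dense output for delay lookups, and post-processing
    utilities (error norms, experimental orders of convergence, equilibration
    and synchronization times, ternary-plot coordinates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
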