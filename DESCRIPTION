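Package: bactaxis
Title: Minimal Models of Metabolism-Based and Metabolism-Independent
    Bacterial Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a minimal bistable autocatalytic metabolism coupled
    to idealized behavioral controllers that regulate the concentration of
    an environmental resource: a metabolism-independent resource homeostat,
    two metabolism-based controllers (metabolite concentration and its rate
    of change), and a sigmoidal switch combining the two sensitivities.
    Provides analytic equilibrium and bifurcation analysis with viability
    classification of states, event-detecting integration of the coupled
    system, survivability maps over initial-condition lattices, a
    survival-based fitness function with exhaustive lattice search and a
    microbial genetic algorithm for parameter optimization, and a 1-D
    spatial population simulation of chemotaxing agents on a fixed resource
    gradient with walls and per-agent error bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
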