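Package: lacpop
Title: Deterministic and Stochastic Cell-Population Simulation of an
    Artificial lac Operon Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of growing, dividing bacterial cell
    populations carrying an artificial lac operon genetic switch. Provides a
    fully stochastic engine (Gillespie-type simulation with time-varying cell
    volume, stochastic DNA duplication, division and partitioning), a hybrid
    engine with deterministic per-cell reaction kinetics between stochastic
    duplication/division events (a piecewise-deterministic Markov process),
    single-lineage (cell chain) sampling, a structured continuum model of the
    lumped biotic phase with closed-form estimators of the cycle-averaged
    surface-to-volume ratio and operator concentration, steady-state and
    bifurcation analysis of the switch, and distribution analysis tools
    (number density functions, mode splitting, heavy-tail statistics,
    Kolmogorov-Smirnov comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
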