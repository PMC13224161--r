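Package: natps
Title: Nonadiabatic Transition Path Sampling with Time-Reversible
    Surface Hopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic, time-reversible nonadiabatic molecular dynamics
    for two-state systems using the mapping approach to surface hopping
    (MASH), combined with a transition path sampling (TPS) engine for
    harvesting rare reactive trajectories between configurational basins.
    Provides a coupled-harmonic avoided-crossing model, an energy-conserving
    integrator with in-step hop detection by root search, Boltzmann sampling
    of the extended nuclear-electronic phase space, shooting-move Monte Carlo
    in trajectory space with flexible path length, path-space temperature
    annealing, and analysis tools for transition times, hop statistics,
    coherence angles, path densities and sampling efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
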