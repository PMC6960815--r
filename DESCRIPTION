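Package: sbris
Title: Constant-pH and Constant-Charge Monte Carlo Simulation of Weak
    Flexible Polyelectrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single weak flexible polyelectrolyte with the
    site-binding rotational-isomeric-state (SBRIS) model, which couples
    discrete proton-binding states with trans/gauche dihedral states,
    harmonic bond stretching and bending, Debye-Hueckel screened
    electrostatics, hard-sphere excluded volume and an applied stretching
    force.  Sampling is by Metropolis Monte Carlo either at constant pH
    (semi-grand canonical, fluctuating charge) or at constant smeared
    charge.  The package computes titration curves, binding capacitance,
    gauche-state probabilities, persistence lengths and force-extension
    curves, provides an exact enumeration oracle for small chains, and
    fits the low-force linear and Pincus scaling laws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
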