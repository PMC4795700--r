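Package: gefcycle
Title: Mass-Action and Quasi-Steady-State Models of G Protein Regulation
    by GEFs and GTPase Activity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic models of the reversible guanine-nucleotide
    exchange factor (GEF) mechanism acting on a G protein, with optional
    intrinsic or GAP-mediated GTPase activity. Provides the full
    six-species mass-action model, a King-Altman (directed spanning tree)
    quasi-steady-state reduction to a single equation, closed-form
    steady-state solutions and their monotonicity properties, stimulation
    protocol simulations of the futile activation/inactivation cycle, a
    thermodynamically consistent synthetic parameter generator, and a small
    command-line interface for simulation, reduction, parameter handling
    and invariant checking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
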