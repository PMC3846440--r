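Package: sbmlfuse
Title: Composition and Kinetic Simulation of SBML Models
Version: 0.1.0
Authors@R:
    person("PathCase", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Merge ("fuse") two SBML models into a single flat model by
    matching compartments, species and reactions through MIRIAM annotations
    and exact effective names, with deterministic identifier-conflict
    renaming, conflict warnings and per-source id maps. Includes a kinetic
    ODE simulator (adaptive Dormand-Prince with an independent fixed-step
    reference integrator), a reaction-scheme model generator producing
    SBML-Test-Suite-style fixture models, similarity reports between
    models, experimental time-course overlay, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
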