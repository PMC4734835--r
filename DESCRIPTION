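Package: gemflux
Title: Portable Representation, Consistency Checking and Constraint-Based
    Simulation of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with genome-scale metabolic models (GEMs):
    a modular, version-control-friendly YAML model format with include
    support; import of SBML (levels 1-3, standard or COBRA dialect, with
    strict and repair modes) and tab-delimited reaction tables; export to
    SBML and delimited text; detection of stoichiometric inconsistencies
    by compound- and reaction-based mass-consistency linear programs;
    flux-consistency (blocked reaction) detection by FVA sweep or FASTCC;
    formula and charge balance checks; constraint-based simulation (flux
    balance analysis with optional thermodynamic loop removal, flux
    variability analysis, robustness curves, random minimal networks);
    and GapFind/GapFill gap analysis.  A bundled bounded-variable simplex
    and branch-and-bound solver backs all linear and mixed-integer
    programs; alternative solver backends can be registered.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    igraph,
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
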