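Package: metacage
Title: Metadynamics, Minimum-Energy Paths, Committors and Electric-Field
    Decomposition for Nanocage Electrostatic Catalysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis chain for explaining electrostatic
    catalysis of reductive elimination inside supramolecular hosts:
    reconstruction of well-tempered metadynamics free-energy surfaces from
    deposited Gaussian hills, zero-temperature string-method minimum-energy
    paths with transition-state location, committor validation of candidate
    transition-state ensembles by stochastic shooting, transition-state-theory
    rate ratios, and decomposition of the electrostatic activation free energy
    into per-source-group bond-dipole/electric-field contributions. A
    synthetic-data module (model potentials, overdamped Langevin dynamics,
    grouped point-charge environments with analytic fields) provides ground
    truth so every stage is testable without ab initio molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
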