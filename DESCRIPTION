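Package: rblfer
Title: Residue-Based Linear Free Energy Relationship Analysis of Two-State
    Protein Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for residue-resolved rate-equilibrium free energy
    relationship (REFER) analysis of two-state conformational exchange in
    proteins. Builds and classifies REFER regressions of residue-specific
    forward and backward rate constants against equilibrium constants,
    quantifies the geometry of the log k versus log k' scatter with 95%
    confidence ellipses and a flatness statistic, detects collectively
    deviating residues by iteratively reweighted robust regression with
    Tukey bisquare weights, simulates the fake-linearity artifact that the
    triadic constraint K = k/k' can induce, and implements the two-process
    (Linderstrom-Lang) hydrogen-exchange kinetic model with per-residue
    fitting of opening and closing rates across a pH ladder. Synthetic-data
    generators produce every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
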