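Package: ramanmix
Title: Deconvolution of Conformational Exchange from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting solution Raman spectra of flexible small
    biomolecules (e.g. RNA nucleosides) as mixtures of conformer sub-spectra.
    Includes synthesis of broadened Raman spectra from harmonic vibrational
    mode tables, spectral estimation from polarizability time series via the
    autocorrelation-function route, glycosidic-torsion and ribose
    pseudorotation analysis of trajectories with population and exchange-rate
    estimation, experimental preprocessing (background subtraction,
    asymmetric-least-squares baseline), and a regularized multi-start
    mixture fit whose weights are interpreted as conformer populations.
    Seeded synthetic-data generators provide ground-truth inputs for every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
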