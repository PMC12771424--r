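Package: HbKinetics
Title: Coordination State and Ligand-Binding Kinetics of Hexacoordinate Hemoglobins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectro-kinetic analysis of plant and animal hexacoordinate
    hemoglobins. Estimates the ferrous heme coordination equilibrium (fraction
    hexacoordinate and K_H) from visible absorbance spectra via the empirical
    A555/A540 ratio, fits single-exponential kinetic traces from flash
    photolysis and stopped-flow ligand-displacement experiments to derive
    bimolecular O2/CO association rates, CO-competition-corrected O2
    dissociation rates and O2 affinities, and measures autoxidation rates of
    the oxy complex. Includes a mass-action simulator of the
    hexacoordinate-globin kinetic scheme that generates every observable the
    analysis consumes (equilibrium spectra, transient-absorption and
    stopped-flow traces, autoxidation spectral series) with known ground
    truth, so each stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
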