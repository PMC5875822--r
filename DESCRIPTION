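Package: iortbio
Title: Radiobiological Modelling of Spherical-Applicator kV Intraoperative Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiobiological analysis of low-kV intraoperative
    radiotherapy (IORT) delivered through a spherical applicator placed in a
    lumpectomy cavity. Reconstructs the radial dose field from printed anchor
    points using an inverse-square times attenuation model, represents residual
    cancer-cell infiltration profiles (half-Gaussian or linear) and
    modified-linear-quadratic (MLQ) radiosensitivity parameter sets, computes
    dose-protraction factors and cell survival, averages survival over
    concentric spherical shells, inverts the survival equation for the
    equivalent uniform dose (EUD), and derives therapeutic ratios (TR) against
    a uniform-dose comparator. Includes a scenario-grid runner, paper-style
    table rendering, and a quadrature uncertainty budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
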