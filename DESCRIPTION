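Package: flexwave
Title: Passive Spectroscopy and Guided-Wave Dispersion of Natural Pulse
    Waves in Blood Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to extract phase-velocity dispersion and time-of-flight
    velocities of the two natural pulse waves guided along blood vessels:
    the symmetric (longitudinal, L(0,1)-type) pulse wave and the slow,
    dispersive antisymmetric (flexural, F(1,1)-type) pulse wave.
    Implements passive spectroscopy by phase-only noise correlation
    (monochromatic and polychromatic focal spots with sinusoidal
    wavelength fits), correlation-based time-of-flight estimation with
    directional filtering, sum/difference separation of symmetric and
    antisymmetric wall motion, and a numerical solver for the Gazis
    characteristic equation of a traction-free hollow elastic cylinder
    (Muller's method) together with the low-frequency closed forms and
    the Moens-Korteweg relation. A seeded synthetic-data generator
    emulates vessel power-Doppler movies and two-wall displacement
    records at retinal and carotid scales so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
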