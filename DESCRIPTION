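Package: axonpearl
Title: Membrane Mechanics and Action-Potential Conduction in Nanopearled Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the pearls-on-a-string (nanopearled) morphology
    of unmyelinated axons and its functional consequences. Provides a seeded
    synthetic-data generator for pearled radius profiles, STED-like intensity
    profiles and serial-section stacks; inflection-point morphometry of
    nonsynaptic varicosities (NSVs) and connectors with full-width
    half-maximum, spacing-periodicity and three-dimensional Pythagorean
    corrections; an axisymmetric Helfrich membrane-shape relaxer coupling
    bending rigidity, surface tension and van 't Hoff osmotic pressure; and a
    generalized cable-equation Hodgkin-Huxley simulator on radius-varying
    geometries with uniform or 190-nm periodic sodium-channel layouts,
    including conduction-velocity readouts, dimension sweeps and
    velocity predictions from measured geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    tools,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
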