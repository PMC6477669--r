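Package: padmech
Title: Mechanical Characterization of Calcaneal Fat Pad Surrogates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing elastomeric surrogates of the calcaneal
    (heel) fat pad from uniaxial compression tests. Converts machine records
    (time, displacement, force) to engineering stress-stretch curves, fits the
    incompressible uniaxial Yeoh hyperelastic model by multi-start nonlinear
    least squares with R-squared reporting, segments cyclic load-unload
    records and computes the energy dissipation ratio (EDR) with a peak-load
    repeatability check, and selects surrogate compositions by R-squared
    correlation of force-strain curves against reference curves on a common
    grid. A seeded synthetic-data generator produces machine-format records
    from the forward model so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
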