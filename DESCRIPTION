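Package: patchyllps
Title: Buffer-Specific Liquid-Liquid Phase Separation of Globular Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamics of liquid-liquid phase separation (LLPS) in globular
    protein solutions using Wertheim's first-order thermodynamic perturbation
    theory (TPT1) for a hard sphere decorated with equivalent short-range
    square-well association sites. Provides state functions (monomer fraction,
    Helmholtz free energy, osmotic pressure, chemical potential, second virial
    coefficient), spinodal/binodal/critical-point solvers and cloud-point
    prediction, calibration of buffer- and salt-specific square-well depths
    against cloud-point data, reduction of dynamic/static light scattering and
    capillary viscometry measurements to the interaction diffusion coefficient
    kD, the osmotic second virial coefficient B22 and the Jones-Dole viscosity
    B coefficient, and seeded synthetic-data generators for every measurement
    stream.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
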