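Package: aortaphantom
Title: Material Characterization and Compliance-Based Design of Aortic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing compliant vascular phantoms for in vitro
    hemodynamic testing. Implements one-term Ogden and Holzapfel-Gasser-Ogden
    (HGO) hyperelastic strain-energy models with exact incompressible stress
    responses under uniaxial and equibiaxial loading, least-squares calibration
    of constitutive parameters from stress-strain test curves, static inflation
    of a thick-walled hyperelastic tube with compliance and distensibility
    computation for wall-thickness selection, a pulsatile aortic-inlet flow
    waveform generator, and post-processing metrics (helicity, kinetic energy,
    normalized velocity profiles, peak timing) for gridded velocity fields.
    Synthetic-data generators for mechanical test curves and analytic flow
    fields make the full pipeline testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
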