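Package: viscopulse
Title: Pressure-Pulse Attenuation in Viscoelastic Vascular Conduits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the damping of pressure pulses travelling along thin-walled
    viscoelastic tubes such as polymeric vascular grafts. Implements Maxwell and
    Zener (standard linear solid) wall constitutive models, closed-form modal
    decay spectra (including the Cardano/trigonometric roots of the third-order
    Moore-Gibson-Thompson-type pressure equation and its essential spectrum),
    method-of-lines simulation of the damped wave equations with a heartbeat
    inlet pulse, constitutive parameter identification from cyclic stress/strain
    records by orthogonal-distance Nelder-Mead fitting, and inverse design maps
    of the material properties required for a target attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
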