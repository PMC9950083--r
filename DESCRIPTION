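Package: domescatter
Title: Infrared Extinction of Dome- and Semi-Capsule-Shaped Scatterers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the infrared extinction efficiency of substrate-deformed
    cell-like scatterers (domes and semi-capsules) in the anomalous-diffraction
    (van de Hulst) approximation, with an exact Mie-series reference for
    spheres. Generates Kramers-Kronig-consistent complex refractive-index
    spectra from Lorentz band specifications, and reproduces the
    sphere-subspace (ME-EMSC meta-model) reconstruction experiment: a PCA
    basis built from van de Hulst sphere extinction curves is used to
    reconstruct semi-capsule extinction curves, including a peak-shift
    negative control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
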