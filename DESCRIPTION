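Package: tracheadrs
Title: Monte Carlo Modelling and Spectral Inversion for Tracheal Diffuse
    Reflectance Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Layered Monte Carlo simulation of visible-light (500-600 nm)
    transport in the tracheal wall with a contact fiber-optic probe
    geometry, together with the diffuse-reflectance-spectroscopy
    processing chain used for intraoperative blood-supply assessment:
    attenuation spectra, nonnegative hemoglobin unmixing yielding tissue
    oxygen saturation (StO2), and a chord-subtended blood-filling index.
    Includes packaged tracheal optical properties, a synthetic clinical
    spectrum generator, scripted simulation experiments (perichondrium
    oxygenation contrast, layer-thickness sweeps, saturation and
    blood-filling sweeps with parameter recovery), and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
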