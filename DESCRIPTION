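Package: floremis
Title: Floral Infrared Emissivity Estimation from Thermal-Camera Point Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the thermal-infrared emissivity of flowers
    (or other small biological targets) from thermal-camera point measurements
    of targets at a known temperature. Implements the Stefan-Boltzmann
    radiometric forward model with reflected-temperature and air-path
    transmissivity terms, closed-form and root-solved emissivity inversion,
    the two field protocols in common use (thermocouple contact and water-bath
    flotation), fixed-emissivity temperature retrieval (the T0.98 convention),
    grouped summary statistics, and a synthetic measurement generator with
    realistic sensor noise and protocol bias artefacts for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
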