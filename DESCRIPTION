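Package: sfaox
Title: Spectral Filter Array Imaging Pipeline and Occlusion Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for snapshot mosaic multispectral (spectral
    filter array) cameras applied to dynamic skin oxygenation imaging. Provides
    dark/white flat-field correction, spatial rearrangement of 4x4 mosaic
    frames into 16-band cubes, a basis-function spectral correction that maps
    imperfect Fabry-Perot channel responses (second-order lobes, crosstalk)
    onto virtual narrow-band reflectance samples, and a modified Beer-Lambert
    delta-concentration estimator for oxy- and deoxy-hemoglobin during a
    vascular occlusion test. A built-in forward simulator generates ground
    truth occlusion dynamics, skin reflectance spectra, mosaic sensor frames
    and a slow reference oximeter trace so every stage is testable without
    hardware or clinical data. Curve analytics cover feature scaling, moving
    averages, cuff-release alignment, de-/re-saturation slope fitting and
    RMSE/GFC agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    splines,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
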