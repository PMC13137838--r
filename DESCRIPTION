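Package: junctiondyn
Title: Quantitative Analysis of Endothelial Cell-Cell Junction Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for endothelial monolayer
    mechanobiology: watershed segmentation of junction-marker
    (VE-cadherin) fluorescence images, per-cell morphometrics (area,
    perimeter, ellipse-fit aspect ratio, orientation), junctional-band
    intensity quantification within a fixed-width region of interest
    around the segmented cell border, border-displacement dynamics
    d-mean(t)/(2*dt), structure-tensor apparent coherency and dominant
    direction, trans-endothelial resistance normalization, and
    Kelvin-Voigt fitting of post-ablation recoil curves. Includes a
    seeded synthetic monolayer and time-lapse generator with exact
    ground truth so every stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
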