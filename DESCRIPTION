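Package: nbiseg
Title: Narrow-Band Spectral Imaging Analysis and Segmentation of Microsurgical Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for narrow-band (hyperspectral) reflectance imaging of
    microsurgical tissue types: white/dark reference calibration of spectral
    image cubes, polygon annotation handling in the VGG Image Annotator JSON
    dialect, per-wavelength nonparametric screening (Shapiro-Wilk normality,
    Mann-Whitney rank tests) with consolidation of significant wavelength
    ranges, optimal spectral band selection by affinity pruning and
    per-wavelength divergence ranking with Savitzky-Golay smoothing, and a
    compact U-Net style convolutional encoder-decoder for tissue segmentation
    scored by Jaccard IoU. Includes a synthetic scene generator that emulates
    annotated tissue boards with known ground truth, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    mgcv
Config/testthat/edition: 3
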