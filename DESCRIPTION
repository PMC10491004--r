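Package: holophase
Title: Phase Compensation and Reconstruction for Off-Axis Digital
    Holographic Microscopy in Non-Telecentric Regime
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phase imaging from a single off-axis hologram
    recorded with a non-telecentric digital holographic microscope. From
    the hologram plus only the camera pixel pitch and the laser
    wavelength, the package estimates the interference tilt from the
    centroid of the +1 diffraction order and the curvature of the
    residual spherical wavefront from the size of its compact support,
    filters the +1 order, compensates tilt and sphere with digital
    reference and conjugated spherical waves, locates the sphere centre
    by Otsu binarization and region eccentricity, and optionally
    fine-tunes the spherical parameters by minimizing a wrap-count or
    phase-standard-deviation cost with a family of box-constrained
    minimizers including a hybrid genetic-algorithm plus pattern-search
    scheme. A forward hologram simulator with ground-truth manifests,
    reliability-sorting 2D phase unwrapping, SSIM and percent-error
    metrics, a dual-shot subtraction baseline and a command-line
    interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    png,
    yaml,
    grDevices,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
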