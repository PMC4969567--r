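Package: cbctsat
Title: Depth-Camera Guided Correction of Detector Saturation in Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-backed toolkit for correcting overexposure
    (detector saturation) artifacts in short-scan cone-beam CT using
    surface geometry from a consumer depth camera. Provides an analytic
    phantom simulator (cone-beam forward projection, detector saturation
    model, depth-camera rendering), a sphere-scaffold cross-calibration
    pipeline that estimates the rigid transform between depth-camera and
    CT coordinates, projection-domain extrapolation of saturated detector
    rows from closed B-spline surface models, and a Feldkamp-Davis-Kress
    (FDK) short-scan reconstruction chain with Parker weighting and
    region-of-interest evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
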