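Package: stereofid
Title: Fiducial-Based Co-Registration and Stereotactic Targeting Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the targeting accuracy of MRI-guided
    stereotactic implantation. Implements the closed-form least-squares
    (unit-quaternion) solution to the absolute orientation problem for
    co-registering pre- and post-operative fiducial coordinate sets, with
    optional isotropic scaling; fiducial re-positioning (registration
    residual) statistics; detection of spherical fiducial markers and
    cannula-tip hypointensities in 3-D intensity volumes; per-axis and
    Euclidean target-error analysis for an implantation cohort; and a
    synthetic-data generator that simulates fiducial arcs, scan pairs under
    known rigid motion and localization noise, and partial-volume sphere
    rasterization on anisotropic voxel grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
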