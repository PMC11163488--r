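Package: dvfmend
Title: Finite-Element Correction and Quality Assessment of Deformable
    Image Registration Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and reducing interior uncertainty in
    displacement vector fields (DVFs) produced by deformable image
    registration (DIR), aimed at adaptive-radiotherapy quality assurance.
    Provides axis-aligned 3-D image, label-map and vector-field containers
    with Jacobian-determinant calculus and backward warping; a regular
    tetrahedral mesh with linear-elastic finite-element solves driven by
    prescribed node displacements; a hybrid correction that replaces the
    organ-interior of an existing DVF with the elasticity solution implied
    by its own boundary displacements; a contour-matching registration that
    derives boundary constraints from structure surfaces; registration
    metrics (DICE, mean distance to agreement, Jacobian statistics,
    one-tailed Wilcoxon-Mann-Whitney comparisons); dose warping with
    DVH/V_x summaries; and a synthetic phantom generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
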