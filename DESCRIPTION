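Package: jointkin
Title: Automated Joint Kinematics from Dynamic CT Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for estimating in-vivo joint kinematics
    from dynamic (4D) computed tomography. Bones are segmented on a
    reference frame by multi-atlas registration and label fusion (majority
    vote, globally and locally ranked normalized cross-correlation),
    anatomical landmarks are propagated from the atlases, each bone is
    tracked through the dynamic sequence by masked sequential rigid
    registration, and joint rotations are reported as cardan angles between
    bone-embedded reference frames. Includes a three-stage (rigid, affine,
    B-spline free-form) intensity-based registration engine with stochastic
    gradient descent, segmentation and landmark validation metrics (Dice,
    overlap error fractions, surface distances, Hausdorff distance, target
    registration error), agreement statistics (Bland-Altman limits of
    agreement, intraclass correlation), and a synthetic joint phantom
    generator providing exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
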