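Package: aaastrain
Title: Averaged Wall-Motion Models and Local Strain Analysis for 4D
    Ultrasound Imaging of Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-resolved three-dimensional (4D)
    ultrasound speckle-tracking exports of abdominal aortic aneurysm
    (AAA) wall motion.  Multiple manual segmentations of one acquisition
    are combined into an averaged wall-motion model by cylindrical
    unwrapping, homogeneous re-meshing and isoparametric tracking of the
    re-mesh points through the cardiac cycle.  Local in-plane Biot
    strains are computed per quadrilateral wall element, reduced to
    peak-to-peak amplitudes and summarised by distribution indices.
    Bounded rigid and affine iterative-closest-point registration aligns
    the ultrasound geometry with a CT-derived wall and calcification
    point cloud, after which strain amplitudes in calcified and
    non-calcified wall regions are compared with a one-sided
    Mann-Whitney U test.  A synthetic phantom generator provides
    pulsating aneurysm geometries with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
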