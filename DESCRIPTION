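Package: hybridreg
Title: Hybrid Free-Form Deformation and Viscous-Fluid Deformable Image
    Registration for CT/CBCT Volumes
Version: 0.1.0
Authors@R:
    person("hybridreg", "developers", email = "hybridreg@example.org",
           role = c("aut", "cre"))
Description: Deformable image registration of 3D grayscale volumes in which
    a sparse-control-point cubic B-spline free-form deformation provides the
    initial warp estimate and a convolution-simplified viscous-fluid stage,
    driven by a mutual-information force field, refines it to a dense
    per-voxel displacement. Includes a multi-resolution pyramid pipeline,
    intensity similarity metrics (mutual information, normalized
    cross-correlation, mean absolute difference), contour-propagation
    evaluation (Dice coefficient, Hausdorff distance, centroid target
    registration error, paired t-test), NIfTI/MetaImage input and output,
    a command-line interface, and a synthetic CT/CBCT phantom generator
    with ground-truth deformations so every component is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
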