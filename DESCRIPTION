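Package: siamreg
Title: Cross-Scale Weakly Supervised Deformable Registration with a Siamese U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable registration of 3D multi-modal image volumes with
    different grid sizes. A Siamese 3D U-Net with weight-shared encoders
    extracts features from fixed and moving volumes; a feature-level
    zero-padding module aligns moving-branch feature extents to the fixed
    branch so that cross-size pairs are registered without pre-cropping; the
    decoder emits a dense displacement vector field on the fixed grid.
    Training is weakly supervised: a multi-scale Gaussian-smoothed soft Dice
    loss on anatomical label overlap plus a displacement-smoothness penalty,
    optimised with Adam. Includes NIfTI I/O and geometric preprocessing,
    a synthetic bifurcating-vessel phantom generator with ground-truth
    elastic deformation fields, Dice / landmark-distance / target
    registration error metrics, grouped k-fold splitting, and command-line
    entry points for simulation, training, registration and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
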