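Package: mcdreg
Title: Deformable 3D Image Registration with Monte Carlo Dropout Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of 3D medical images with a
    Bayesian fully convolutional network. The network predicts a dense
    displacement field from a stacked source/target pair and is trained with a
    normalized cross-correlation image loss, a displacement-smoothness
    penalty, and an anti-folding penalty on negative Jacobian determinants.
    Keeping dropout active at test time (Monte Carlo Dropout) yields a
    posterior sample of displacement fields whose per-voxel spread estimates
    registration uncertainty, useful for flagging out-of-distribution inputs
    such as lesioned brains. Includes a spatial transformer (trilinear warp),
    Jacobian/folding analytics, group normalization, labeled synthetic
    phantoms with ground-truth deformations, and evaluation metrics (Dice,
    folding counts, and NPV/TPR/UA uncertainty-quality sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
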