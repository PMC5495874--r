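Package: emegfem
Title: Calibrated Finite-Element Forward Modeling and Combined EEG/MEG Source
    Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for electrophysiological source imaging on hexahedral
    finite-element head models. Builds geometry-adapted hexahedral meshes from
    labeled voxel volumes, assigns isotropic or diffusion-tensor-derived
    anisotropic conductivity, assembles the trilinear FEM stiffness matrix and
    solves EEG/MEG forward problems with Venant dipole sources, transfer
    matrices and an algebraic-multigrid preconditioned conjugate-gradient
    solver. Includes closed-form multilayer-sphere EEG and Sarvas MEG oracles
    for forward validation, combined EEG/MEG skull-conductivity calibration by
    dipole scanning, sLORETA source localization of averaged epileptic
    discharges with F-value thresholding and clustering, and export of cluster
    peaks as cuboid regions of interest for targeted high-resolution MR
    imaging. A synthetic phantom module generates labeled head volumes, sensor
    arrays, diffusion tensors and evoked/epoch recordings with controlled
    noise for fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
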