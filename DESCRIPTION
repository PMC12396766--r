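Package: avfcfd
Title: Hemodynamics of Arteriovenous Fistulas from Synthetic Micro-CT Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale implementation of a micro-CT based computational
    fluid dynamics (CFD) workflow for murine arteriovenous fistula (AVF)
    hemodynamics. Parametric AVF phantoms (artery, stenotic fistula, ballooning
    vein) are voxelized into contrast-CT-like volumes, segmented by
    thresholding and seeded region growing, and reduced to centerline diameter
    profiles. Pulsatile Doppler-like waveforms are converted to parabolic
    inlet boundary conditions and driven through an incompressible
    Navier-Stokes projection solver on structured staggered grids
    (axisymmetric stenotic tube and planar T-junction). The package computes
    the standard hemodynamic statistics of vascular CFD: wall shear stress,
    time-averaged wall shear stress (TAWSS), oscillatory shear index (OSI),
    Q-criterion vortex fields, flow splits, pressure-drop localization,
    Poiseuille resistance, and TAWSS-diameter correlations, together with
    grid-convergence and periodicity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    igraph,
    RNifti,
    jsonlite,
    rlang,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
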