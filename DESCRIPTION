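Package: lcbp
Title: Loss-Compensated Back-Propagation Imaging for Intravascular Microwave Catheters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and qualitative image reconstruction for catheter-based
    intravascular microwave imaging of coronary-artery wall anomalies. Provides a
    Born-approximation multistatic forward model for a conformal dipole array in
    lossy blood, the cylindrical-harmonic (Hankel/Bessel series) Green's function
    of a lossy medium with a central conducting rod, loss-compensated
    back-propagation (LC-BP) reconstruction on 2D planes and full 3D voxel grids
    with antenna-pattern and polarization weighting, additive white Gaussian
    noise at a prescribed SNR, differential (reference minus target) imaging,
    and detection metrics (connected components, localization error, ghost
    ambiguity ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
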