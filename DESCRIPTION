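Package: cyclesct
Title: Hybrid Phantom Calibration and CycleGAN Synthetic CT from CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for generating synthetic CT (sCT) from cone-beam CT (CBCT)
    for adaptive radiotherapy workflows. Implements a hybrid pipeline:
    phantom-based Hounsfield-unit calibration (HU-to-relative-electron-density
    curves from a nine-insert calibration phantom, composed into a CBCT-to-CT
    HU correction), followed by unpaired image translation with a 2D CycleGAN
    (ResNet generators, patch discriminators, least-squares adversarial and L1
    cycle-consistency losses) written on small Rcpp convolution kernels.
    Includes digital head-phantom and CBCT-degradation simulators for fully
    synthetic end-to-end experiments, and the quantitative evaluation stack:
    masked MAE/ME, HU line profiles, DVH parameters (D2, D98, Dmean, Dmax),
    global 3D gamma analysis with sub-voxel search, and Wilcoxon signed-rank
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
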