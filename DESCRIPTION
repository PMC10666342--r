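Package: cinebands
Title: Simulation and Dual-Stage Neural Suppression of bSSFP Banding and
    Flow Artifacts in Cardiac Cine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying joint suppression of balanced steady-state
    free precession (bSSFP) banding artifacts and flow ghosts in cardiac
    cine MRI. Provides a physics-based numerical phantom that renders
    frequency-sweep cine movies with dark bands and phase-encoding flow
    ghosts; short-range phase-cycling (SPC) and full-range phase-cycling
    (FPC) label synthesis; a sigmoid voxel-identity (VI) soft label; a
    dual-stage 3D U-Net (a VI sub-network that classifies artifacts and a
    frozen-VI-conditioned artifact-suppression sub-network) trained with a
    two-stage procedure; and evaluation utilities (ROI signal flatness
    across offsets, voxelwise interpretability correlation, SPC-vs-FPC
    residual comparison, Wilcoxon / Bland-Altman / ICC reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
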