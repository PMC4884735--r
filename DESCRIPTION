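Package: ficdmap
Title: Fiber Connectivity Density Mapping on the Cortical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs vertex-wise fiber connectivity density (FiCD) maps of
    the cortex from diffusion-tensor data: parcellation of the gray-white
    matter interface into approximately equal-area cortical units, seeded
    deterministic streamline tractography with FA, turning-angle and
    fiber-length termination rules, the FiCD statistic (summed per-fiber mean
    FA normalised by seed volume), surface-based Gaussian smoothing and
    Z-transformation, vertex-wise two-group general linear models with Monte
    Carlo cluster-wise correction, and post-hoc region-of-interest statistics
    (group tests, partial correlations, cluster-seeded fiber counts). Includes
    synthetic tensor-field, cortical-mesh and cohort phantom generators with
    known ground truth so every stage is testable without MRI data, plus
    NIfTI, GIFTI, TrackVis and TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
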