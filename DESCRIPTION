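Package: dwidown
Title: Down-Sampling of Multi-Shell Diffusion MRI Gradient Schemes with
    DTI and NODDI Tractometry Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to subsample multi-shell diffusion-gradient schemes by
    generalized electrostatic-repulsion subset selection, fit diffusion
    tensor (FA, MD, RD) and NODDI (ICvf, ISOvf, OD) microstructure models,
    compute along-bundle tractometry profiles, and quantify agreement
    between reference and down-sampled acquisitions (relative L1 distance,
    Kolmogorov-Smirnov tests with FDR correction, Bland-Altman limits of
    agreement, white-matter volume loss). Includes a seeded synthetic
    multi-shell phantom generator with Rician noise for end-to-end study
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
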