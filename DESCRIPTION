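Package: helicalTF
Title: Tensor-Framelet Regularized Iterative Reconstruction for Multislice
    Helical CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for iterative reconstruction of multislice
    helical (spiral) cone-beam CT. Provides a matched helical cone-beam
    forward projector and exact numerical adjoint (Joseph-style ray driving
    with optional flying focal spot), a multilevel 3D tensor-framelet tight
    frame transform with isotropic shrinkage, an ADMM (split-Bregman) solver
    with total-variation and simplified helical FDK baselines, an analytic
    phantom and Poisson transmission scan simulator with sparse-view
    subsampling, and the standard image-quality metrics (UQI, SNR, CNR, MTF
    from an edge profile).
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
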