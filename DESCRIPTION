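Package: esskit
Title: Effective Stoichiometric Space Inference from Single-Cell Snapshot Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers stoichiometric structure of mass-action reaction networks
    from the covariance of log-transformed single-cell multiplex snapshots.
    Provides chemical reaction network representations (stoichiometric
    subspaces, deficiency, weak reversibility, mass-action kinetics), random
    complex-balanced and gene-regulatory network generators, stiff ODE
    ensemble simulation of single-cell-like snapshots, eigengap detection on
    log-space covariance spectra, extraction of the effective stoichiometric
    space with row reduction under complete pivoting, principal-angle
    comparison of subspaces, Gaussian-mixture subpopulation gating, and
    resampling tools (entry-distribution null model, bootstrap confidence
    intervals for net-reaction vectors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
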