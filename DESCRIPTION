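Package: orthosignal
Title: Modeling and Design of Orthogonal Quorum-Sensing Communication Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering two-channel acyl-homoserine-lactone (AHL)
    cell-cell communication systems with minimal crosstalk. Implements an
    equilibrium transcription transfer function for promoters activated by
    LuxR/LasR receiver proteins bound to 3OC6HSL or 3OC12HSL (with a full
    mass-action steady-state oracle), ratiometric promoter-activity
    extraction from multi-channel plate-fluorometer time series, Bayesian
    inference of binding constants and receiver expression levels via an
    affine-invariant ensemble MCMC sampler, a signal-to-crosstalk optimizer
    over receiver expression space, and a compartment-based
    reaction-diffusion simulator of discrete cell populations on gridded
    membranes, including relay devices, stripe propagation assays and
    positive-feedback bifurcation scans. A synthetic-data generator emulates
    both plate-fluorometer and grid-membrane experiments with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
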