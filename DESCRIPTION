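Package: kernelscape
Title: Multiscale Random-Forest Habitat Models and Resistant-Kernel
    Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scale-optimized species distribution modelling and
    landscape connectivity analysis on gridded landscapes. Implements
    spatial thinning of occurrence records and constrained pseudo-absence
    generation, FRAGSTATS-style moving-window landscape metrics and
    multiscale covariate stacks, a two-step equal-sampling multiscale
    random-forest habitat model (univariate scale optimization,
    collinearity screening, Model Improvement Ratio subsetting), a
    negative-exponential suitability-to-resistance transform, resistant
    kernel and factorial least-cost-path connectivity engines, core
    habitat extraction and protected-area coverage accounting, plus a
    seeded synthetic-landscape generator with a known suitability model
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
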