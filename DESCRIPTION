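Package: mppdeconv
Title: Deconvolution of Calcium Imaging Movies with Marked Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative-model deconvolution of calcium imaging movies.
    The movie is modelled as a linear-Gaussian state space with jumps driven
    by a marked point process whose marks are fluorescent footprints and
    whose intensity is modulated by an external stimulus through a mixture
    of Gaussian mark kernels and Gaussian or von Mises stimulus kernels,
    with a truncated weighted-gamma-process prior on the mixing measure.
    Coordinate-ascent variational inference jointly recovers cell
    footprints, 0-1 spike trains, firing rates and stimulus tuning curves
    from the raw movie. Includes a simulator for stimulus-tuned neurons,
    evaluation utilities (F-measures for spike and ROI detection,
    chi-squared threshold detection, inhomogeneous-Poisson tuning-curve
    maximum likelihood, correlation images), movie patching for large
    fields of view, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    optparse,
    mclust,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
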