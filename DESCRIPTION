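Package: linecooc
Title: Line Co-Occurrence Statistics and Perceptual Grouping of Curvilinear Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns shift-twist invariant line co-occurrence kernels from
    centerlines of curvilinear structures (e.g. retinal blood vessels),
    computes the time-integrated Fokker-Planck resolvent of Mumford's
    direction process on positions and orientations together with its
    symmetrization to the projective line bundle, fits the stochastic model
    to the learned statistics, and uses the resulting connectivity kernel
    inside a self-tuning spectral clustering pipeline that groups
    interrupted and crossing vessels into individual perceptual units.
    Includes orientation-score lifting with cake wavelets, a Monte Carlo
    simulator of the direction process, and synthetic phantom generators
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
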