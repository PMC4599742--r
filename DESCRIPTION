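Package: rbfCME
Title: Adaptive Gaussian Radial Basis Function Collocation for the Chemical
    Master Equation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Direct numerical solution of chemical master equations (CMEs) for
    reaction networks with multi-stable probability landscapes. The
    distribution is parametrised by collocation on Gaussian radial basis
    functions whose centres track the time-evolving essential support of the
    solution: the support boundary is represented by a signed distance
    function on the state lattice, regularised by an alpha-hull, and
    extrapolated between time steps with a level-set scheme. The package also
    provides an exact sparse full-state-space solver (generator assembly,
    stationary distributions, transients by the action of the matrix
    exponential), a Gillespie stochastic simulation baseline with occupancy
    extraction, and built-in models for a self-regulating gene, bistable and
    tristable toggle switches, and an osteochondral stem-cell differentiation
    switch.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'lattice.R'
    'models.R'
    'config.R'
    'generator.R'
    'expmv.R'
    'basis.R'
    'geometry.R'
    'adaptive.R'
    'ssa.R'
    'io.R'
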