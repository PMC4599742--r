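#' Number of states enumerated by a lattice box
#' @param box a [LatticeBox-class]
#' @return integer state count \eqn{N = \prod_k ((u_k-l_k)/s + 1)}
#' @export
setGeneric("nStates", function(box) standardGeneric("nStates"))

#' Extract the lattice box of an object
#' @param x an object holding a lattice box
#' @export
setGeneric("latticeBoxOf", function(x) standardGeneric("latticeBoxOf"))

#' Extract tabulated lattice values
#' @param x a distribution or signed distance field
#' @param asArray reshape to a `d`-dimensional array?
#' @export
setGeneric("latticeValues",
           function(x, asArray = FALSE) standardGeneric("latticeValues"))

#' Assemble the exact CME generator on a truncation box
#'
#' @param network a [ReactionNetwork-class]
#' @param box a step-1 [LatticeBox-class] containing the states of interest
#' @return a [GeneratorMatrix-class] whose columns sum to zero exactly
#' @export
setGeneric("assembleGenerator",
           function(network, box) standardGeneric("assembleGenerator"))

#' Stationary distribution of a truncated CME generator
#' @export
setGeneric("steadyState", function(gen, ...) standardGeneric("steadyState"))

#' Transient solution by the action of the matrix exponential
#' @export
setGeneric("evolve", function(gen, u0, t, ...) standardGeneric("evolve"))

#' Interpolate nodal values into basis coefficients
#' @param basis a [BasisSystem-class]
#' @param nodalValues one value per basis centre
#' @return a [CoefficientVector-class] reproducing the values at the nodes
#' @export
setGeneric("interpolate",
           function(basis, nodalValues) standardGeneric("interpolate"))

#' Essential support of a distribution
#'
#' The set of states whose probability strictly exceeds `pThreshold`.
#' @export
setGeneric("essentialSupport",
           function(u, pThreshold) standardGeneric("essentialSupport"))

#' Count connected components of a lattice set
#'
#' Face (von Neumann, 2d-neighbour) connectivity, matching the unit-step
#' reachability of the CME.
#' @export
setGeneric("connectedComponents",
           function(S, ...) standardGeneric("connectedComponents"))

#' Euclidean l2 distance between two tabulated distributions
#' @export
setGeneric("l2Error", function(u, ref) standardGeneric("l2Error"))

#' Mass-preserving moving-average smoothing over the 3^d neighbourhood
#' @export
setGeneric("smoothBox3", function(u) standardGeneric("smoothBox3"))
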