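#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib rbfCME, .registration = TRUE
NULL

#' Axis-aligned truncation of the copy-number lattice
#'
#' A `LatticeBox` is a finite, axis-aligned window of the copy-number state
#' space \eqn{\mathbb{N}^d}, together with a fixed enumeration of its states.
#' Boxes with `step > 1` represent coarser sub-lattices (used as candidate
#' grids for basis-function centres); all geometric quantities on such a box
#' (distances, alpha-hull radii, inflation margins) are expressed in units of
#' one grid step.
#'
#' States are enumerated column-major along increasing axis index: the first
#' axis varies fastest. `latticePoints()` materialises the enumeration,
#' `stateIndex()`/`indexState()` convert between states and indices.
#'
#' @slot d number of species (axes).
#' @slot lower,upper inclusive integer bounds per axis.
#' @slot step lattice spacing (identical on every axis).
#' @export
setClass("LatticeBox",
  representation(d = "integer", lower = "integer", upper = "integer",
                 step = "integer"),
  validity = function(object) {
    if (length(object@lower) != object@d || length(object@upper) != object@d)
      return("lower/upper must have length d")
    if (any(object@upper < object@lower))
      return("upper must be >= lower componentwise")
    if (length(object@step) != 1L || object@step < 1L)
      return("step must be a single integer >= 1")
    if (any((object@upper - object@lower) %% object@step != 0L))
      return("(upper - lower) must be divisible by step on every axis")
    TRUE
  })

#' A single reaction channel
#'
#' @slot shift integer stoichiometric vector \eqn{\nu} of length `d`; one
#'   firing moves the state from `x` to `x + shift`.
#' @slot propensity vectorised function mapping an `n x d` state matrix to
#'   `n` non-negative rates \eqn{a(x)}.
#' @slot name channel label.
#' @export
setClass("ReactionChannel",
  representation(shift = "integer", propensity = "function",
                 name = "character"))

#' A reaction network (stoichiometry plus propensities)
#'
#' @slot d species count.
#' @slot channels ordered list of [ReactionChannel-class] objects.
#' @slot name model label (e.g. `"toggle2d"`).
#' @slot params named list of the rate constants the network was built from.
#' @slot components optional labels of a discrete (non-copy-number)
#'   component; when present, the last axis of the lattice indexes the
#'   component (0-based), and the channel propensities encode the
#'   inter-component coupling.
#' @export
setClass("ReactionNetwork",
  representation(d = "integer", channels = "list", name = "character",
                 params = "list", components = "character"),
  validity = function(object) {
    for (ch in object@channels) {
      if (!is(ch, "ReactionChannel")) return("channels must be ReactionChannel")
      if (length(ch@shift) != object@d)
        return("every stoichiometric vector must have length d")
    }
    TRUE
  })

#' A probability distribution tabulated on a lattice box
#'
#' @slot box the [LatticeBox-class] carrying the enumeration.
#' @slot values one value per enumerated state.
#' @export
setClass("LatticeDistribution",
  representation(box = "LatticeBox", values = "numeric"),
  validity = function(object) {
    if (length(object@values) != nStates(object@box))
      return("values length must equal the state count of the box")
    TRUE
  })

#' Sparse CME generator on a truncated lattice
#'
#' The operator realises
#' \deqn{(Lu)(x) = \sum_i a_i(x-\nu_i) u(x-\nu_i) - a_i(x) u(x)}
#' with conserving truncation: a channel whose target state leaves the box
#' contributes no flux, so every column of the matrix sums to zero exactly
#' and total probability is conserved on the box.
#'
#' @slot box the truncation box (`step` must be 1).
#' @slot matrix sparse `N x N` generator (`Matrix::dgCMatrix`).
#' @slot network name of the originating model, for provenance.
#' @export
setClass("GeneratorMatrix",
  representation(box = "LatticeBox", matrix = "Matrix", network = "character"))

#' Gaussian radial basis system with interpolation matrix
#'
#' Basis function `j` is the anisotropic Gaussian
#' \deqn{\phi_j(x) = \prod_k \exp(-(x_k - c_{jk})^2 / \sigma_{jk})}
#' and the interpolation matrix has entries \eqn{A_{ij} = \phi_j(x^i)} over
#' the centres \eqn{x^i}. The inverse is formed once at construction and
#' reused by every coefficient-space operator.
#'
#' @slot centres `n x d` matrix of centre coordinates.
#' @slot sigma `n x d` matrix of connectivity parameters (squared-length
#'   units).
#' @slot A,Ainv the interpolation matrix and its inverse.
#' @slot kappa estimated condition number of `A`.
#' @export
setClass("BasisSystem",
  representation(centres = "matrix", sigma = "matrix", A = "matrix",
                 Ainv = "matrix", kappa = "numeric"))

#' Coefficients of a basis expansion
#'
#' Represents \eqn{\tilde u(x) = \sum_i \alpha_i \phi_i(x)}.
#'
#' @slot basis the [BasisSystem-class].
#' @slot alpha coefficient vector, one entry per basis function.
#' @export
setClass("CoefficientVector",
  representation(basis = "BasisSystem", alpha = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != nrow(object@basis@centres))
      return("alpha length must match the basis size")
    TRUE
  })

#' Collocation discretisation of a CME generator
#'
#' @slot basis the collocation basis.
#' @slot matrix dense `n x n` coefficient-space operator.
#' @export
setClass("DiscretizedGenerator",
  representation(basis = "BasisSystem", matrix = "matrix"))

#' Boolean subset of a lattice box
#'
#' @slot box the (possibly coarse, `step > 1`) lattice box.
#' @slot mask logical vector over the box enumeration.
#' @export
setClass("SupportMask",
  representation(box = "LatticeBox", mask = "logical"),
  validity = function(object) {
    if (length(object@mask) != nStates(object@box))
      return("mask length must equal the state count of the box")
    TRUE
  })

#' Signed Euclidean distance field of an alpha-hull region
#'
#' Values are distances (in grid-step units) to the boundary of the
#' alpha-regularised region: negative inside, positive outside. The zero
#' sublevel set recovers the region exactly on the lattice.
#'
#' @slot box the lattice box.
#' @slot values one signed distance per state (`Inf` everywhere if the
#'   region is empty).
#' @slot alpha the alpha-hull radius the field was built with (grid units).
#' @export
setClass("SignedDistanceField",
  representation(box = "LatticeBox", values = "numeric", alpha = "numeric"))

#' Parameters of the adaptive collocation solver
#'
#' See [adaptiveConfig()] for the meaning and defaults of each field.
#' @export
setClass("AdaptiveConfig",
  representation(pThreshold = "numeric", dtInit = "numeric", gamma = "numeric",
                 alpha = "numeric", gridStep = "integer", massTol = "numeric",
                 supportTol = "numeric", dtShrink = "numeric",
                 maxRejects = "integer", sigmaC = "numeric",
                 conditionCap = "numeric", steadyTol = "numeric",
                 maxSteps = "integer", evalCutoff = "numeric",
                 maxBasisSize = "integer"))

#' Per-step record of an adaptive run
#'
#' @slot steps data frame with one row per accepted step: time `t`, degrees
#'   of freedom `n`, total mass, support discrepancy of the validated
#'   prediction, rejected attempts, support component count and the
#'   essential-support threshold in force.
#' @slot masks list of accepted [SupportMask-class] objects (one per row).
#' @slot config the [AdaptiveConfig-class] used.
#' @export
setClass("AdaptiveRunLog",
  representation(steps = "data.frame", masks = "list",
                 config = "AdaptiveConfig"))

#' Result of an adaptive solve
#'
#' @slot basis,alpha final collocation representation.
#' @slot support final essential support on the candidate grid.
#' @slot log the [AdaptiveRunLog-class].
#' @slot box the full (step-1) state-space box.
#' @slot t the time actually reached.
#' @slot steady whether the run stopped on steady-state detection.
#' @export
setClass("AdaptiveResult",
  representation(basis = "BasisSystem", alpha = "numeric",
                 support = "SupportMask", log = "AdaptiveRunLog",
                 box = "LatticeBox", t = "numeric", steady = "logical"))

#' A Gillespie SSA trajectory
#'
#' Stored states may be thinned for long runs; exact waiting-time-weighted
#' and visit-count occupancy tallies over the full (unthinned) trajectory
#' are always accumulated during simulation.
#'
#' @slot states `m x d` matrix of (possibly thinned) visited states, first
#'   row is the initial state.
#' @slot waitTimes holding time of each stored state (thinned runs store the
#'   total time spent between stored snapshots).
#' @slot thin thinning factor (1 = every jump stored).
#' @slot seed RNG seed used.
#' @slot box truncation box of the table-driven simulation.
#' @slot occupancyTime,occupancyCount unnormalised occupancy tallies over
#'   all steps.
#' @slot nSteps number of reaction events simulated.
#' @slot absorbed `TRUE` if an absorbing state ended the run early.
#' @export
setClass("SSATrajectory",
  representation(states = "matrix", waitTimes = "numeric", thin = "integer",
                 seed = "integer", box = "LatticeBox",
                 occupancyTime = "numeric", occupancyCount = "numeric",
                 nSteps = "numeric", absorbed = "logical"))

#' Hill-type toggle-switch parameters (2-D bistable or 3-D tristable)
#'
#' @slot rates the constants `c1..c6` (2-D) or `c1..c9` (3-D).
#' @slot exps Hill exponents (`beta, gamma` or `beta, gamma, zeta`).
#' @slot d 2 or 3.
#' @export
setClass("ToggleParams",
  representation(rates = "numeric", exps = "numeric", d = "integer"),
  validity = function(object) {
    need <- if (object@d == 2L) 6L else 9L
    if (length(object@rates) != need)
      return(sprintf("%d rate constants required for d=%d", need, object@d))
    if (length(object@exps) != object@d)
      return("one Hill exponent per species required")
    if (any(object@rates <= 0)) return("all rate constants must be positive")
    if (any(object@exps < 1)) return("Hill exponents must be >= 1")
    TRUE
  })

#' Osteochondral switch (OCS) parameters
#'
#' Auto-activation `a`, basal activity `b`, inflection point `m`,
#' inhibition strengths `c..`, decay `k` for the osteogenic (`o`),
#' chondrogenic (`c`) and progenitor (`p`) factors, Hill coefficient
#' `beta`, and pro-osteogenic stimulus `zo >= 0`.
#' @export
setClass("OCSParams",
  representation(ao = "numeric", ac = "numeric", ap = "numeric",
                 bo = "numeric", bc = "numeric", bp = "numeric",
                 mo = "numeric", mc = "numeric", mp = "numeric",
                 coo = "numeric", ccc = "numeric", cpp = "numeric",
                 coc = "numeric", cco = "numeric", cop = "numeric",
                 ccp = "numeric", ko = "numeric", kc = "numeric",
                 kp = "numeric", beta = "numeric", zo = "numeric"),
  validity = function(object) {
    vals <- c(object@ao, object@ac, object@ap, object@bo, object@bc,
              object@bp, object@mo, object@mc, object@mp, object@coo,
              object@ccc, object@cpp, object@coc, object@cco, object@cop,
              object@ccp, object@ko, object@kc, object@kp, object@beta,
              object@zo)
    if (any(!is.finite(vals)) || any(vals < 0))
      return("all parameters must be finite and non-negative")
    if (object@mo <= 0 && object@coo <= 0 && object@coc <= 0 &&
        object@cop <= 0)
      return("denominator of the osteogenic Hill function can vanish")
    if (object@mc <= 0 && object@ccc <= 0 && object@cco <= 0 &&
        object@ccp <= 0)
      return("denominator of the chondrogenic Hill function can vanish")
    if (object@mp <= 0 && object@cpp <= 0)
      return("denominator of the progenitor Hill function can vanish")
    TRUE
  })

#' Self-regulating gene parameters
#'
#' Production rates in the free (`gOn`) and repressed (`gOff`) state,
#' degradation rate `k`, repressor release rate `f`, binding rate constant
#' `h`, and the binding stoichiometry (`"monomer"`: rate `h x`; `"dimer"`:
#' rate `h/2 x (x-1)`).
#' @export
setClass("GeneModelParams",
  representation(gOn = "numeric", gOff = "numeric", k = "numeric",
                 f = "numeric", h = "numeric", bindingMode = "character"),
  validity = function(object) {
    if (any(c(object@gOn, object@gOff, object@k, object@f, object@h) <= 0))
      return("all rates must be positive")
    if (!object@bindingMode %in% c("monomer", "dimer"))
      return("bindingMode must be 'monomer' or 'dimer'")
    TRUE
  })
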