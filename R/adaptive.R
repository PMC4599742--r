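#' Configuration of the adaptive collocation solver
#'
#' @param pThreshold essential-support probability cutoff (applied to the
#'   normalised distribution). The solver may lower it automatically when
#'   the total-mass check fails, as prescribed by the mass-deviation
#'   safeguard.
#' @param dtInit initial and nominal time step: a cleanly accepted step
#'   resumes it, a step accepted after rejections regrows towards it
#'   gradually.
#' @param gamma inflation margin around the predicted support, in units of
#'   one candidate-grid step: a protective layer of basis functions wide
#'   enough to interpolate the density at the boundary.
#' @param alpha alpha-hull radius in grid-step units (lower bound 1,
#'   conventional value 2).
#' @param gridStep spacing of the candidate-centre lattice in copy-number
#'   units (1 resolves every state; coarser grids suit wide distributions).
#' @param massTol accepted relative deviation of total probability from the
#'   initial mass.
#' @param supportTol accepted support discrepancy (grid units) between the
#'   predicted and the computed essential support.
#' @param dtShrink factor (<1) applied to the step on rejection.
#' @param maxRejects abort after this many consecutive rejections.
#' @param sigmaC kernel width factor: `sigma = (sigmaC * gridStep)^2`.
#'   Larger values improve smoothness of the interpolant but worsen the
#'   conditioning of the interpolation matrix.
#' @param conditionCap conditioning cap passed to [makeBasis()].
#' @param steadyTol early stop when the maximal nodal change per unit time
#'   falls below this value (0 disables detection).
#' @param maxSteps hard cap on accepted steps.
#' @param evalCutoff per-kernel truncation used for dense-lattice
#'   evaluation (mass integrals, final distributions).
#' @param maxBasisSize refuse basis systems larger than this (the dense
#'   factorisation is cubic in the basis size).
#' @return an [AdaptiveConfig-class]
#' @export
adaptiveConfig <- function(pThreshold = 1e-5, dtInit = 100, gamma = 2,
                           alpha = 2, gridStep = 1L, massTol = 0.01,
                           supportTol = 2, dtShrink = 0.5, maxRejects = 12L,
                           sigmaC = 1.2, conditionCap = 1e8, steadyTol = 0,
                           maxSteps = 5000L, evalCutoff = 1e-14,
                           maxBasisSize = 4000L) {
  stopifnot(pThreshold > 0, dtInit > 0, gamma >= 0, alpha >= 1,
            gridStep >= 1, massTol > 0, supportTol > 0,
            dtShrink > 0, dtShrink < 1, maxRejects >= 1, sigmaC > 0)
  new("AdaptiveConfig", pThreshold = pThreshold, dtInit = dtInit,
      gamma = gamma, alpha = alpha, gridStep = as.integer(gridStep),
      massTol = massTol, supportTol = supportTol, dtShrink = dtShrink,
      maxRejects = as.integer(maxRejects), sigmaC = sigmaC,
      conditionCap = conditionCap, steadyTol = steadyTol,
      maxSteps = as.integer(maxSteps), evalCutoff = evalCutoff,
      maxBasisSize = as.integer(maxBasisSize))
}

# coarse candidate-centre grid covering the solver box
geometryBox <- function(box, gridStep) {
  up <- box@lower + ((box@upper - box@lower) %/% gridStep) * gridStep
  latticeBox(box@lower, up, step = gridStep)
}

#' Relative deviation of total probability
#'
#' \eqn{(\sum u_0 - \sum u)/\sum u_0}: the mass-conservation diagnostic the
#' adaptive solver monitors after every accepted step.
#'
#' @param u0Mass initial total mass (> 0)
#' @param uMass current total mass
#' @return signed relative deviation
#' @export
massDeviation <- function(u0Mass, uMass) {
  if (u0Mass <= 0) stop("initial mass must be positive")
  (u0Mass - uMass) / u0Mass
}

basisOnRegion <- function(gBox, region, config) {
  centres <- latticePoints(gBox)[region@mask, , drop = FALSE]
  if (nrow(centres) > config@maxBasisSize)
    stop(sprintf(paste0("adaptive basis would need %d centres ",
                        "(cap %d); increase gridStep or pThreshold"),
                 nrow(centres), config@maxBasisSize))
  makeBasis(centres, sigma = (config@sigmaC * config@gridStep)^2,
            conditionCap = config@conditionCap)
}

interpolantMass <- function(basis, alphaC, box, config) {
  # integrate the interpolant over the integer lattice within reach of the
  # kernels (each Gaussian is truncated at evalCutoff)
  r <- ceiling(sqrt(-log(config@evalCutoff) * max(basis@sigma)))
  lo <- pmax(box@lower, apply(basis@centres, 2L, min) - r)
  hi <- pmin(box@upper, apply(basis@centres, 2L, max) + r)
  sub <- latticeBox(lo, hi, 1L)
  sum(evaluateOnLattice(basis, alphaC, sub, cutoff = config@evalCutoff))
}

#' Initialise the adaptive solver
#'
#' Computes the essential support of the (normalised) initial distribution,
#' inflates its alpha-hull by `gamma`, and places basis centres on every
#' candidate-grid point of the inflated region. If the resulting
#' interpolant misses `u0` by more than `pThreshold` anywhere on the
#' fine lattice around the support, the candidate grid is refined (up to
#' two halvings) before giving up.
#'
#' @param network a [ReactionNetwork-class]
#' @param u0 initial distribution: a [LatticeDistribution-class] or a
#'   vectorised function of the state matrix (normalised internally).
#' @param box the step-1 truncation box.
#' @param config an [AdaptiveConfig-class]
#' @return internal solver state (list), also the input of
#'   [advanceAdaptive()]
#' @export
initializeAdaptive <- function(network, u0, box, config = adaptiveConfig()) {
  if (is.function(u0)) u0 <- latticeDistribution(box, u0, normalize = TRUE)
  stopifnot(is(u0, "LatticeDistribution"))
  u0v <- u0@values / sum(u0@values)
  for (attempt in 0:2) {
    gridStep <- max(1L, config@gridStep %/% as.integer(2L^attempt))
    cfg <- config
    cfg@gridStep <- gridStep
    gBox <- geometryBox(box, gridStep)
    gIdx <- stateIndex(box, latticePoints(gBox))
    gv <- u0v[gIdx]
    S0 <- new("SupportMask", box = gBox, mask = gv > cfg@pThreshold)
    if (!any(S0@mask))
      stop("initial distribution has empty essential support at pThreshold")
    region <- sublevelSet(signedDistance(S0, cfg@alpha), cfg@gamma)
    basis <- basisOnRegion(gBox, region, cfg)
    cIdx <- stateIndex(box, basis@centres)
    alphaC <- as.numeric(basis@Ainv %*% u0v[cIdx])
    # verify the interpolant against u0 on the fine lattice near the support
    r <- ceiling(sqrt(-log(cfg@evalCutoff) * max(basis@sigma)))
    lo <- pmax(box@lower, apply(basis@centres, 2L, min) - r)
    hi <- pmin(box@upper, apply(basis@centres, 2L, max) + r)
    sub <- latticeBox(lo, hi, 1L)
    ut <- evaluateOnLattice(basis, alphaC, sub, cutoff = cfg@evalCutoff)
    uref <- u0v[stateIndex(box, latticePoints(sub))]
    icErr <- max(abs(ut - uref))
    if (icErr < cfg@pThreshold) {
      mass0 <- interpolantMass(basis, alphaC, box, cfg)
      log0 <- data.frame(t = 0, n = nrow(basis@centres), mass = mass0,
                         discrepancy = 0, rejects = 0L,
                         components = connectedComponents(S0)$count,
                         pThreshold = cfg@pThreshold)
      return(list(network = network, box = box, gBox = gBox, config = cfg,
                  basis = basis, alphaC = alphaC, S = S0, SPrev = NULL,
                  t = 0, tPrev = NA_real_, dt = cfg@dtInit, mass0 = mass0,
                  pThr = cfg@pThreshold, steps = list(log0),
                  masks = list(S0), steady = FALSE, icError = icErr))
    }
  }
  stop(sprintf(paste0("initial interpolant error %.3g exceeds pThreshold ",
                      "%.3g even after grid refinement; decrease gridStep ",
                      "or increase sigmaC"), icErr, config@pThreshold))
}

#' Advance the adaptive solver by one accepted step
#'
#' Implements one cycle of the adaptive strategy: extrapolate the support
#' via the level-set scheme (the first step integrates on the initial
#' support), build the basis on the gamma-inflated alpha-hull of
#' (current support) \eqn{\cup} (prediction), transfer the coefficients by
#' evaluating the old interpolant at the new centres, advance them with
#' the collocation exponential, then validate: the computed essential
#' support must match the prediction within `supportTol`, and the total
#' mass must stay within `massTol` of the initial mass. A support failure
#' shrinks the step by `dtShrink`; a mass failure halves the
#' essential-support threshold. After `maxRejects` consecutive failures
#' the solver aborts with diagnostics.
#'
#' @param state solver state from [initializeAdaptive()] (or a previous
#'   `advanceAdaptive` call)
#' @return the updated state
#' @export
advanceAdaptive <- function(state) {
  cfg <- state$config
  net <- state$network
  dt <- state$dt
  pThr <- state$pThr
  rejects <- 0L
  oldGrid <- gridValuesOf(state)
  lastRegion <- NULL
  basis <- NULL; aNew <- NULL; Ltil <- NULL
  repeat {
    if (dt < cfg@dtInit * 1e-9)
      stop(sprintf(paste0("time step collapsed at t=%.6g after %d ",
                          "rejections: the support-validation noise floor ",
                          "exceeds supportTol (%.3g); increase supportTol ",
                          "or alpha"), state$t, rejects, cfg@supportTol))
    tNext <- state$t + dt
    SPred <- if (is.null(state$SPrev)) state$S else
      extrapolateSupport(state$SPrev, state$S, state$tPrev, state$t, tNext,
                         alpha = cfg@alpha,
                         maxDisplacement = cfg@gamma + cfg@alpha)
    U <- new("SupportMask", box = state$gBox,
             mask = state$S@mask | SPred@mask)
    dU <- signedDistance(U, cfg@alpha)
    region <- sublevelSet(dU, cfg@gamma)
    # strict interior of the basis region: a support that stays in here was
    # never clipped by the truncation to the region
    safeMask <- sublevelSet(dU, cfg@gamma - 1)@mask
    if (is.null(lastRegion) || !identical(region@mask, lastRegion)) {
      # basis and collocation operator depend only on the region, which is
      # often unchanged across dt retries - reuse them when possible
      basis <- basisOnRegion(state$gBox, region, cfg)
      aNew <- as.numeric(basis@Ainv %*%
                           evaluateBasis(state$basis, state$alphaC,
                                         basis@centres))
      Ltil <- discretizeGenerator(basis, net)
      lastRegion <- region@mask
    }
    stepped <- expmvKrylov(Ltil@matrix, aNew, dt, tol = 1e-10)
    nodal <- as.numeric(basis@A %*% stepped)
    gv <- numeric(nStates(state$gBox))
    gv[stateIndex(state$gBox, basis@centres)] <- nodal
    Sn <- new("SupportMask", box = state$gBox, mask = gv > pThr)
    mass <- interpolantMass(basis, stepped, state$box, cfg)
    mdev <- massDeviation(state$mass0, mass)
    disc <- if (any(Sn@mask)) supportDiscrepancy(Sn, SPred, cfg@alpha)
            else Inf
    # the prediction is validated against the computed support; a computed
    # support that stayed strictly inside the gamma-inflated basis region
    # is also acceptable (the prediction was conservative and the solution
    # was never clipped) - without this, a broad probability shoulder
    # crossing the threshold tangentially can reject every step length
    contained <- any(Sn@mask) && !any(Sn@mask & !safeMask)
    okSupp <- disc <= cfg@supportTol || contained
    okMass <- abs(mdev) <= cfg@massTol
    if (okSupp && okMass) {
      comp <- connectedComponents(Sn)$count
      row <- data.frame(t = tNext, n = nrow(basis@centres), mass = mass,
                        discrepancy = disc, rejects = rejects,
                        components = comp, pThreshold = pThr)
      state$SPrev <- state$S; state$S <- Sn
      state$tPrev <- state$t; state$t <- tNext
      state$basis <- basis; state$alphaC <- stepped
      # a clean step resumes the nominal step size; after rejections the
      # step regrows gradually so that consecutive intervals stay
      # comparable, which the level-set speed estimate relies on
      state$dt <- if (rejects == 0L) cfg@dtInit else
        min(cfg@dtInit, 2 * dt)
      state$pThr <- pThr
      state$steps <- c(state$steps, list(row))
      state$masks <- c(state$masks, list(Sn))
      if (cfg@steadyTol > 0) {
        both <- !is.na(oldGrid)
        chg <- max(abs(gv[both] - oldGrid[both])) / dt
        state$steady <- chg < cfg@steadyTol
      }
      return(state)
    }
    rejects <- rejects + 1L
    if (rejects > cfg@maxRejects)
      stop(sprintf(paste0("step at t=%.6g rejected %d times ",
                          "(discrepancy %.3g vs tol %.3g, mass deviation ",
                          "%.3g vs tol %.3g); decrease dtInit or ",
                          "pThreshold"),
                   state$t, rejects, disc, cfg@supportTol, mdev,
                   cfg@massTol))
    # a shorter step always reduces both failure modes during a transient;
    # a persistently failing mass check signals genuine probability loss
    # through the support boundary, which only a lower threshold cures
    dt <- dt * cfg@dtShrink
    if (!okMass && rejects >= 3L) pThr <- pThr / 2
  }
}

gridValuesOf <- function(state) {
  gv <- rep(NA_real_, nStates(state$gBox))
  gv[stateIndex(state$gBox, state$basis@centres)] <-
    as.numeric(state$basis@A %*% state$alphaC)
  gv
}

#' Solve a CME with the adaptive collocation strategy
#'
#' Runs [initializeAdaptive()] followed by repeated [advanceAdaptive()]
#' until `tEnd` is reached, the solution is detected stationary
#' (`steadyTol`), or `maxSteps` accepted steps have been taken.
#'
#' @param network a [ReactionNetwork-class]
#' @param u0 initial distribution (function or
#'   [LatticeDistribution-class])
#' @param tEnd final time (> 0)
#' @param box step-1 truncation [LatticeBox-class]
#' @param config an [AdaptiveConfig-class]
#' @param verbose print a line per accepted step?
#' @return an [AdaptiveResult-class]
#' @examples
#' \donttest{
#' net <- buildToggle2d()
#' box <- latticeBox(c(0, 0), c(300, 300))
#' u0 <- function(s) exp(-((s[,1] - 133)^2 + (s[,2] - 133)^2) / 266)
#' cfg <- adaptiveConfig(pThreshold = 2e-5, dtInit = 250, gridStep = 6L,
#'                       steadyTol = 1e-9)
#' res <- solveAdaptive(net, u0, tEnd = 8000, box = box, config = cfg)
#' dofTrace(res)[, c("t", "n", "mass", "components")]
#' }
#' @export
solveAdaptive <- function(network, u0, tEnd, box, config = adaptiveConfig(),
                          verbose = FALSE) {
  if (tEnd <= 0) stop("tEnd must be positive")
  state <- initializeAdaptive(network, u0, box, config)
  nsteps <- 0L
  while (state$t < tEnd * (1 - 1e-12) && !state$steady &&
         nsteps < config@maxSteps) {
    state$dt <- min(state$dt, tEnd - state$t)
    state <- advanceAdaptive(state)
    nsteps <- nsteps + 1L
    if (verbose) {
      last <- state$steps[[length(state$steps)]]
      message(sprintf(
        "t=%.6g n=%d mass=%.6f disc=%.2f comps=%d rejects=%d",
        last$t, last$n, last$mass, last$discrepancy, last$components,
        last$rejects))
    }
  }
  log <- new("AdaptiveRunLog", steps = do.call(rbind, state$steps),
             masks = state$masks, config = state$config)
  new("AdaptiveResult", basis = state$basis, alpha = state$alphaC,
      support = state$S, log = log, box = state$box, t = state$t,
      steady = state$steady)
}

#' Per-step log of an adaptive run
#'
#' @param x an [AdaptiveResult-class] or [AdaptiveRunLog-class]
#' @return data frame with one row per accepted step (plus the initial
#'   state): time, degrees of freedom, total mass, support discrepancy,
#'   rejected attempts, support component count, threshold in force
#' @export
dofTrace <- function(x) {
  if (is(x, "AdaptiveResult")) x <- x@log
  x@steps
}

#' Evaluate an adaptive result on the full integer lattice
#'
#' @param result an [AdaptiveResult-class]
#' @param box target box (defaults to the solver box)
#' @return a [LatticeDistribution-class]
#' @export
adaptiveDistribution <- function(result, box = NULL) {
  if (is.null(box)) box <- result@box
  latticeDistribution(box,
                      evaluateOnLattice(result@basis, result@alpha, box))
}

#' Nodal values of an adaptive result at its basis centres
#'
#' @param result an [AdaptiveResult-class]
#' @return list with `centres` (matrix) and `values`
#' @export
adaptiveNodal <- function(result)
  list(centres = result@basis@centres,
       values = as.numeric(result@basis@A %*% result@alpha))

setMethod("show", "AdaptiveResult", function(object) {
  st <- object@log@steps
  cat(sprintf(paste0("AdaptiveResult: t=%.6g (%s), %d accepted steps, ",
                     "DOF %d (max %d), mass %.6f\n"),
              object@t,
              if (object@steady) "steady" else "tEnd/max-steps",
              nrow(st) - 1L, st$n[nrow(st)], max(st$n),
              st$mass[nrow(st)]))
})

setMethod("show", "AdaptiveRunLog", function(object) {
  cat(sprintf("AdaptiveRunLog: %d accepted steps\n",
              nrow(object@steps) - 1L))
  print(utils::head(object@steps, 10L))
})
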