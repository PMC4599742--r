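#' Gillespie stochastic simulation on a truncation box
#'
#' Direct-method SSA: exponential waiting time with the total rate, channel
#' chosen proportionally to its propensity. The simulation is table-driven:
#' propensities are precomputed on the box by [propensityTable()] with the
#' same conserving-truncation convention as [assembleGenerator()], so the
#' simulated chain is exactly the truncated-generator chain and occupancy
#' estimates are directly comparable with [steadyState()]. The inner loop
#' runs compiled; R's RNG is used, so runs are reproducible via the `seed`
#' argument.
#'
#' @param network a [ReactionNetwork-class]
#' @param x0 initial state (length-`d` vector inside `box`)
#' @param nSteps number of reaction events to simulate
#' @param seed integer RNG seed
#' @param box step-1 truncation [LatticeBox-class]
#' @param thin store every `thin`-th visited state (default: 1 for runs up
#'   to 1e6 steps, else ~1e5 snapshots). Occupancy tallies are always
#'   accumulated over every step.
#' @return an [SSATrajectory-class]
#' @examples
#' net <- buildToggle2d()
#' box <- latticeBox(c(0, 0), c(300, 300))
#' traj <- gillespie(net, c(133, 133), nSteps = 1e4, seed = 1, box = box)
#' occ <- occupancyDistribution(traj, box)
#' @export
gillespie <- function(network, x0, nSteps, seed, box, thin = NULL) {
  stopifnot(nSteps >= 1)
  i0 <- stateIndex(box, as.integer(x0))
  if (is.na(i0)) stop("x0 is outside the box")
  if (is.null(thin)) thin <- if (nSteps <= 1e6) 1L else
    as.integer(ceiling(nSteps / 1e5))
  tab <- propensityTable(network, box)
  sizes <- boxSizes(box)
  mult <- cumprod(c(1L, sizes[-box@d]))
  offsets <- vapply(network@channels,
                    function(ch) as.integer(sum(ch@shift * mult)),
                    integer(1L))
  set.seed(seed)
  res <- ssa_core(tab, offsets, i0 - 1L, as.double(nSteps),
                  as.integer(thin))
  states <- indexState(box, res$snapIdx + 1L)
  new("SSATrajectory", states = states, waitTimes = res$snapWait,
      thin = as.integer(thin), seed = as.integer(seed), box = box,
      occupancyTime = res$occT, occupancyCount = res$occC,
      nSteps = res$stepsDone, absorbed = res$absorbed)
}

#' Occupancy distribution of an SSA trajectory
#'
#' The fraction of simulated time spent in each state (`weight = "time"`,
#' the ergodic estimator of the stationary distribution) or the fraction
#' of visits (`weight = "count"`). For unthinned trajectories the estimate
#' can be recomputed from the stored states (`source = "states"`), which
#' is the slow reference path; by default the exact tallies accumulated
#' during simulation are used.
#'
#' @param traj an [SSATrajectory-class]
#' @param box target [LatticeBox-class] (defaults to the trajectory's box)
#' @param weight `"time"` or `"count"`
#' @param source `"accumulated"` or `"states"`
#' @return a [LatticeDistribution-class] with unit mass; states falling
#'   outside `box` are reported in the `"overflow"` attribute
#' @export
occupancyDistribution <- function(traj, box = NULL,
                                  weight = c("time", "count"),
                                  source = c("accumulated", "states")) {
  weight <- match.arg(weight)
  source <- match.arg(source)
  if (is.null(box)) box <- traj@box
  overflow <- 0
  if (source == "accumulated") {
    if (!identical(boxSizes(box), boxSizes(traj@box)) ||
        !identical(unname(box@lower), unname(traj@box@lower)))
      stop("accumulated tallies exist only on the trajectory's own box")
    w <- if (weight == "time") traj@occupancyTime else traj@occupancyCount
  } else {
    m <- nrow(traj@states) - 1L
    if (m < 1L) stop("trajectory stores no transitions")
    wts <- if (weight == "time") traj@waitTimes else
      rep(traj@thin, length(traj@waitTimes))
    idx <- stateIndex(box, traj@states[seq_len(m), , drop = FALSE])
    inside <- !is.na(idx)
    overflow <- sum(wts[!inside])
    w <- numeric(nStates(box))
    agg <- rowsum(wts[inside], idx[inside])
    w[as.integer(rownames(agg))] <- agg[, 1L]
  }
  tot <- sum(w)
  if (tot <= 0) stop("empty occupancy")
  out <- latticeDistribution(box, w / tot)
  attr(out, "overflow") <- overflow / max(tot + overflow, .Machine$double.xmin)
  out
}

#' @describeIn smoothBox3 moving average over the `3^d` neighbourhood with
#'   edge-truncated, renormalised windows, followed by an exact global mass
#'   rescale (the published smoothing step for SSA occupancy estimates).
#' @export
setMethod("smoothBox3", "LatticeDistribution", function(u) {
  sizes <- boxSizes(u@box)
  d <- u@box@d
  arr <- array(u@values, dim = sizes)
  wgt <- array(1, dim = sizes)
  shiftZero <- function(a, k, s) {
    n <- dim(a)[k]
    if (n == 1L) return(array(0, dim(a)))
    out <- array(0, dim(a))
    src <- lapply(dim(a), seq_len)
    dst <- src
    if (s > 0) { src[[k]] <- seq_len(n - 1L); dst[[k]] <- 2:n }
    else       { src[[k]] <- 2:n;             dst[[k]] <- seq_len(n - 1L) }
    block <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), dst, list(block)))
  }
  sm1 <- function(a, k) a + shiftZero(a, k, 1L) + shiftZero(a, k, -1L)
  for (k in seq_len(d)) {
    arr <- sm1(arr, k)
    wgt <- sm1(wgt, k)
  }
  v <- as.numeric(arr / wgt)
  v <- v * (sum(u@values) / sum(v))
  latticeDistribution(u@box, v)
})

#' @describeIn l2Error Euclidean norm of the difference of the value
#'   arrays.
#' @export
setMethod("l2Error", signature("LatticeDistribution", "LatticeDistribution"),
  function(u, ref) {
    if (!identical(boxSizes(u@box), boxSizes(ref@box)) ||
        !identical(unname(u@box@lower), unname(ref@box@lower)))
      stop("distributions live on different boxes")
    sqrt(sum((u@values - ref@values)^2))
  })

setMethod("show", "SSATrajectory", function(object) {
  cat(sprintf(paste0("SSATrajectory: %.0f steps (thin=%d, %d stored), ",
                     "seed=%d%s\n"),
              object@nSteps, object@thin, nrow(object@states), object@seed,
              if (object@absorbed) ", ended in absorbing state" else ""))
})
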