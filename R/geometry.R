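distanceToSet <- function(box, mask) {
  # Euclidean distance (grid units) from every cell to the nearest TRUE cell
  sqrt(edt_squared(as.logical(mask), as.integer(boxSizes(box))))
}

#' @describeIn essentialSupport states with probability strictly above the
#'   threshold.
#' @export
setMethod("essentialSupport", signature("LatticeDistribution", "numeric"),
  function(u, pThreshold) {
    if (pThreshold < 0) stop("pThreshold must be non-negative")
    new("SupportMask", box = u@box, mask = u@values > pThreshold)
  })

#' Alpha-hull region of a lattice point set
#'
#' Lattice approximation of the alpha-hull: morphological closing of the
#' set with a Euclidean ball of radius `alpha` (dilation then erosion, both
#' realised through exact distance transforms). Small `alpha` preserves
#' holes and keeps clusters farther apart than `2 alpha` disjoint; as
#' `alpha` grows the region tends to the lattice rasterisation of the
#' convex hull.
#'
#' @param points a [SupportMask-class]
#' @param alpha hull radius in grid-step units (lower bound: 1 grid step;
#'   the conventional choice is 2)
#' @return a [SupportMask-class] containing the input set
#' @export
alphaRegion <- function(points, alpha) {
  if (alpha < 1) stop("alpha must be at least one grid step")
  if (!any(points@mask)) return(points)
  dil <- distanceToSet(points@box, points@mask) <= alpha
  clo <- distanceToSet(points@box, !dil) > alpha
  new("SupportMask", box = points@box, mask = clo | points@mask)
}

#' Signed distance field of the alpha-hull of a set
#'
#' Negative inside the alpha-region, positive outside; magnitudes are exact
#' Euclidean lattice distances (grid units) to the nearest cell across the
#' boundary. The zero sublevel set recovers the alpha-region exactly:
#' `sublevelSet(signedDistance(S, a), 0)` equals `alphaRegion(S, a)`.
#'
#' @param region a [SupportMask-class]
#' @param alpha alpha-hull radius in grid units
#' @return a [SignedDistanceField-class]
#' @export
signedDistance <- function(region, alpha) {
  reg <- alphaRegion(region, alpha)@mask
  if (!any(reg))
    return(new("SignedDistanceField", box = region@box,
               values = rep(Inf, nStates(region@box)), alpha = alpha))
  dpos <- distanceToSet(region@box, reg)
  dneg <- distanceToSet(region@box, !reg)
  v <- ifelse(reg, -dneg, dpos)
  v[is.infinite(v) & v < 0] <- -max(boxSizes(region@box)) # full-box region
  new("SignedDistanceField", box = region@box, values = v, alpha = alpha)
}

#' Sublevel set of a signed distance field
#'
#' `{x : d(x) <= level}`. `level = 0` recovers the region itself;
#' `level = gamma > 0` inflates it by a margin `gamma`, which is how the
#' adaptive solver surrounds the essential support with a protective layer
#' of basis functions.
#'
#' @param d a [SignedDistanceField-class]
#' @param level offset in grid units
#' @return a [SupportMask-class]
#' @export
sublevelSet <- function(d, level = 0) {
  new("SupportMask", box = d@box, mask = d@values <= level)
}

#' Union of two regions in signed-distance representation
#'
#' The pointwise minimum of two signed distance fields represents the union
#' of their interior regions (exact on the zero level; the magnitude away
#' from the boundary can overestimate near the medial axis).
#'
#' @param d1,d2 [SignedDistanceField-class] objects on the same box
#' @return a [SignedDistanceField-class]
#' @export
unionRegions <- function(d1, d2) {
  stopifnot(identical(boxSizes(d1@box), boxSizes(d2@box)),
            identical(unname(d1@box@lower), unname(d2@box@lower)))
  new("SignedDistanceField", box = d1@box,
      values = pmin(d1@values, d2@values), alpha = d1@alpha)
}

#' Level-set extrapolation of a moving support
#'
#' Predicts the support at `tNext` by linear extrapolation of the signed
#' distance field through its values at two earlier times (the finite-
#' difference form of the level-set transport equation, exact for rigid
#' translation at constant boundary speed):
#' \deqn{d' = d_i + (t_{i+1}-t_i) \frac{d_i - d_{i-1}}{t_i - t_{i-1}}}
#' thresholded at zero.
#'
#' @param SPrev,SCurr supports at the two earlier times
#' @param tPrev,tCurr,tNext strictly increasing times
#' @param alpha alpha-hull radius used for both distance fields
#' @param maxDisplacement optional cap (grid units) on the magnitude of the
#'   extrapolated boundary displacement; protects against noise in the
#'   finite-difference speed estimate when the look-ahead interval is much
#'   longer than the estimation interval
#' @return predicted [SupportMask-class] at `tNext`
#' @export
extrapolateSupport <- function(SPrev, SCurr, tPrev, tCurr, tNext, alpha = 2,
                               maxDisplacement = Inf) {
  if (!(tPrev < tCurr && tCurr < tNext))
    stop("times must satisfy tPrev < tCurr < tNext")
  if (!any(SPrev@mask) || !any(SCurr@mask)) return(SCurr)
  dp <- signedDistance(SPrev, alpha)
  dc <- signedDistance(SCurr, alpha)
  disp <- (tNext - tCurr) * (dc@values - dp@values) / (tCurr - tPrev)
  disp <- pmin(pmax(disp, -maxDisplacement), maxDisplacement)
  v <- dc@values + disp
  new("SupportMask", box = SCurr@box, mask = v <= 0)
}

#' Discrepancy between two supports
#'
#' Sup-norm of the difference of the two signed distance fields over the
#' union of the two alpha-regions: zero iff the alpha-regions coincide,
#' and approximately the boundary displacement (in grid units) for nearby
#' supports. Used by the adaptive solver to validate predicted supports.
#'
#' @param Sa,Sb [SupportMask-class] objects on the same box
#' @param alpha alpha-hull radius
#' @return non-negative scalar (`Inf` if exactly one support is empty)
#' @export
supportDiscrepancy <- function(Sa, Sb, alpha = 2) {
  stopifnot(identical(boxSizes(Sa@box), boxSizes(Sb@box)))
  ea <- any(Sa@mask); eb <- any(Sb@mask)
  if (!ea && !eb) return(0)
  if (!ea || !eb) return(Inf)
  da <- signedDistance(Sa, alpha)
  db <- signedDistance(Sb, alpha)
  over <- sublevelSet(da, 0)@mask | sublevelSet(db, 0)@mask
  max(abs(da@values[over] - db@values[over]))
}

#' @describeIn connectedComponents face-connectivity component count and
#'   labels.
#' @param S a [SupportMask-class]
#' @return list with `count` and an integer `labels` vector over the box
#'   (0 outside the set)
#' @export
setMethod("connectedComponents", "SupportMask", function(S, ...) {
  idx <- which(S@mask)
  N <- nStates(S@box)
  labels <- integer(N)
  if (!length(idx)) return(list(count = 0L, labels = labels))
  sizes <- boxSizes(S@box)
  d <- S@box@d
  pos <- match(seq_len(N), idx) # state -> vertex id (NA outside)
  edges <- list()
  stride <- 1L
  coords <- indexState(S@box, idx)
  for (k in seq_len(d)) {
    relk <- (coords[, k] - S@box@lower[k]) %/% S@box@step
    can <- relk < sizes[k] - 1L               # neighbour inside the box
    nb <- idx + stride
    ok <- can & S@mask[pmin(nb, N)]
    edges[[k]] <- cbind(pos[idx[ok]], pos[nb[ok]])
    stride <- stride * sizes[k]
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(em)) g <- igraph::add_edges(g, as.integer(t(em)))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(count = comp$no, labels = labels)
})
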