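#' Construct a Gaussian radial basis system
#'
#' Assembles the interpolation matrix \eqn{A_{ij} = \phi_j(x^i)} over the
#' given centres, factorises it (dense inverse, reused by all operators)
#' and estimates its condition number. The connectivity parameter
#' \eqn{\sigma} trades coverage of the state space against conditioning of
#' `A`: wide kernels overlap strongly and `A` approaches singularity,
#' narrow kernels leave gaps between nodes.
#'
#' @param centres `n x d` matrix of distinct centre coordinates (a vector is
#'   taken as a single-axis centre list).
#' @param sigma connectivity parameters in squared-length units: a scalar,
#'   a per-axis vector, or an `n x d` matrix. The conventional choice for
#'   centres on a grid of spacing `h` is `sigma = (c h)^2` with `c` just
#'   below 1; see [adaptiveConfig()].
#' @param conditionCap construction fails when the estimated condition
#'   number exceeds this cap (advice: reduce `sigma` or coarsen centres).
#' @return a [BasisSystem-class]
#' @examples
#' b <- makeBasis(cbind(0:9), sigma = 1)
#' max(abs(b@A %*% b@Ainv - diag(10)))
#' @export
makeBasis <- function(centres, sigma, conditionCap = 1e8) {
  if (is.null(dim(centres))) centres <- cbind(as.numeric(centres))
  centres <- as.matrix(centres)
  storage.mode(centres) <- "double"
  n <- nrow(centres); d <- ncol(centres)
  if (n < 1L) stop("at least one centre is required")
  if (anyDuplicated(asplit(centres, 1L)) > 0L)
    stop("centres must be distinct")
  if (is.null(dim(sigma))) {
    sigma <- matrix(rep_len(as.numeric(sigma), d), n, d, byrow = TRUE)
  }
  if (any(sigma <= 0)) stop("sigma must be positive")
  A <- gbfDesignMatrix(centres, centres, sigma)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("interpolation matrix is numerically singular (",
         conditionMessage(e), "); decrease sigma or use fewer/coarser ",
         "centres"))
  # 1-norm condition estimate, essentially free once the inverse exists
  kap <- norm(A, "1") * norm(Ainv, "1")
  if (!is.finite(kap) || kap > conditionCap)
    stop(sprintf(paste0("interpolation matrix too ill-conditioned ",
                        "(estimate %.3g > cap %.3g); decrease sigma or ",
                        "use fewer/coarser centres"), kap, conditionCap))
  new("BasisSystem", centres = centres, sigma = sigma, A = A, Ainv = Ainv,
      kappa = kap)
}

# phi_j(p_i) for arbitrary evaluation points: rows = points, cols = basis
gbfDesignMatrix <- function(points, centres, sigma) {
  n <- nrow(centres); m <- nrow(points); d <- ncol(centres)
  logA <- matrix(0, m, n)
  for (k in seq_len(d)) {
    diff2 <- outer(points[, k], centres[, k], "-")^2
    logA <- logA - sweep(diff2, 2L, sigma[, k], "/")
  }
  exp(logA)
}

#' @describeIn interpolate coefficients via the factorised interpolation
#'   matrix; exact at the nodes up to factorisation round-off.
#' @export
setMethod("interpolate", signature("BasisSystem", "numeric"),
  function(basis, nodalValues) {
    if (length(nodalValues) != nrow(basis@centres))
      stop("need exactly one nodal value per centre")
    new("CoefficientVector", basis = basis,
        alpha = as.numeric(basis@Ainv %*% nodalValues))
  })

#' Evaluate a basis expansion at arbitrary points
#'
#' @param basis a [BasisSystem-class]
#' @param alpha a [CoefficientVector-class] or plain numeric vector
#' @param points `m x d` matrix of evaluation points
#' @return numeric vector of \eqn{\tilde u(p) = \sum_j \alpha_j \phi_j(p)}
#' @export
evaluateBasis <- function(basis, alpha, points) {
  if (is(alpha, "CoefficientVector")) alpha <- alpha@alpha
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  as.numeric(gbfDesignMatrix(points, basis@centres, basis@sigma) %*% alpha)
}

#' Evaluate a basis expansion on a whole lattice box
#'
#' Accumulates each Gaussian only over the lattice cells where it exceeds
#' `cutoff` (a local patch), which keeps dense-lattice evaluation (mass
#' integrals, essential supports) linear in the basis size.
#'
#' @param basis a [BasisSystem-class]
#' @param alpha coefficients
#' @param box target [LatticeBox-class] (any step)
#' @param cutoff per-kernel truncation level
#' @return a numeric vector over the box enumeration
#' @export
evaluateOnLattice <- function(basis, alpha, box, cutoff = 1e-14) {
  if (is(alpha, "CoefficientVector")) alpha <- alpha@alpha
  d <- ncol(basis@centres)
  stopifnot(box@d == d)
  sizes <- boxSizes(box)
  vals <- numeric(prod(sizes))
  mult <- cumprod(c(1, sizes[-d]))
  logCut <- log(cutoff)
  for (j in seq_len(nrow(basis@centres))) {
    if (alpha[j] == 0) next
    axes <- vector("list", d)
    for (k in seq_len(d)) {
      r <- sqrt(-logCut * basis@sigma[j, k])
      lo <- max(box@lower[k],
                box@lower[k] + box@step *
                  ceiling((basis@centres[j, k] - r - box@lower[k]) / box@step))
      hi <- min(box@upper[k],
                box@lower[k] + box@step *
                  floor((basis@centres[j, k] + r - box@lower[k]) / box@step))
      if (lo > hi) { axes <- NULL; break }
      x <- seq(lo, hi, by = box@step)
      axes[[k]] <- list(
        idx = (x - box@lower[k]) %/% box@step,
        w = exp(-(x - basis@centres[j, k])^2 / basis@sigma[j, k]))
    }
    if (is.null(axes)) next
    # tensor accumulation of the separable kernel over the patch
    patch <- axes[[1L]]$w * alpha[j]
    off <- axes[[1L]]$idx
    if (d > 1L) for (k in 2:d) {
      patch <- outer(patch, axes[[k]]$w)
      off <- outer(off, axes[[k]]$idx * mult[k], "+")
    }
    ix <- as.integer(off) + 1L
    vals[ix] <- vals[ix] + as.numeric(patch)
  }
  vals
}

#' Collocation shift operator in coefficient space
#'
#' The coefficient-space realisation of the lattice shift: nodal values of
#' the shifted interpolant are \eqn{A_1 \alpha} with
#' \eqn{(A_1)_{ij} = \phi_j(x^i - n e_k)}, so the operator returned is
#' \eqn{\tilde T_k^n = A^{-1} A_1}. `n = 0` gives the identity; `|n| > 1`
#' is formed by composing unit shifts, mirroring the operator-power
#' definition of the exact shifts.
#'
#' @param basis a [BasisSystem-class]
#' @param k axis index
#' @param n integer shift power
#' @return dense `n x n` matrix acting on coefficients
#' @export
approxShift <- function(basis, k, n = 1L) {
  d <- ncol(basis@centres)
  stopifnot(k >= 1L, k <= d)
  nb <- nrow(basis@centres)
  if (n == 0L) return(diag(nb))
  unit <- function(sgn) {
    pts <- basis@centres
    pts[, k] <- pts[, k] - sgn
    basis@Ainv %*% gbfDesignMatrix(pts, basis@centres, basis@sigma)
  }
  Tk <- unit(sign(n))
  out <- Tk
  for (i in seq_len(abs(n) - 1L)) out <- Tk %*% out
  unname(as.matrix(out))
}

#' Collocation multiplication operator in coefficient space
#'
#' \eqn{\tilde W_a = A^{-1} \mathrm{diag}\{a(x^1),\ldots,a(x^n)\} A}: maps
#' the coefficients of \eqn{\tilde u} to those of the interpolant of
#' \eqn{a(x)\tilde u(x)} at the nodes (exact at the nodes by construction).
#'
#' @param basis a [BasisSystem-class]
#' @param a propensity: a vectorised function of the state matrix, or a
#'   vector of values at the centres
#' @return dense `n x n` matrix acting on coefficients
#' @export
approxMult <- function(basis, a) {
  av <- if (is.function(a)) as.numeric(a(basis@centres)) else
    rep_len(as.numeric(a), nrow(basis@centres))
  if (any(!is.finite(av))) stop("propensity is not finite at some centre")
  basis@Ainv %*% (av * basis@A)
}

#' Collocation discretisation of the CME generator
#'
#' Assembles \eqn{\tilde L = \sum_i (\prod_k \tilde T_k^{\nu_{ik}} - I)
#' \tilde W_{a_i}} channel by channel from [approxShift()] and
#' [approxMult()].
#'
#' @param basis a [BasisSystem-class] whose centres lie in the model's
#'   admissible region
#' @param network a [ReactionNetwork-class]
#' @return a [DiscretizedGenerator-class]
#' @export
discretizeGenerator <- function(basis, network) {
  stopifnot(ncol(basis@centres) == network@d)
  nb <- nrow(basis@centres)
  Ltil <- matrix(0, nb, nb)
  for (ch in network@channels) {
    W <- approxMult(basis, ch@propensity)
    S <- diag(nb)
    for (k in seq_len(network@d)) {
      if (ch@shift[k] != 0L) S <- approxShift(basis, k, ch@shift[k]) %*% S
    }
    Ltil <- Ltil + (S %*% W - W)
  }
  new("DiscretizedGenerator", basis = basis, matrix = unname(as.matrix(Ltil)))
}

#' Advance collocation coefficients by the exponential of the generator
#'
#' \eqn{\alpha(t + dt) = e^{dt \tilde L} \alpha(t)}, computed by a Krylov
#' approximation of the action of the exponential (the dense exponential is
#' never formed). `dt = 0` returns the coefficients unchanged.
#'
#' @param gen a [DiscretizedGenerator-class]
#' @param alpha a [CoefficientVector-class] (or numeric vector)
#' @param dt duration (>= 0)
#' @param tol local error tolerance of the Krylov stepper
#' @return a [CoefficientVector-class]
#' @export
collocationStep <- function(gen, alpha, dt, tol = 1e-10) {
  if (dt < 0) stop("dt must be non-negative")
  a <- if (is(alpha, "CoefficientVector")) alpha@alpha else as.numeric(alpha)
  if (dt > 0) a <- expmvKrylov(gen@matrix, a, dt, tol = tol)
  new("CoefficientVector", basis = gen@basis, alpha = a)
}

setMethod("show", "BasisSystem", function(object) {
  cat(sprintf("BasisSystem: %d Gaussian centres in %d-D, cond(A) ~ %.3g\n",
              nrow(object@centres), ncol(object@centres), object@kappa))
})

setMethod("show", "DiscretizedGenerator", function(object) {
  cat(sprintf("DiscretizedGenerator: %d x %d (collocation)\n",
              nrow(object@matrix), ncol(object@matrix)))
})
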