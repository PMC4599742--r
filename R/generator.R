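#' Propensity table on a truncation box
#'
#' Evaluates every channel at every box state and zeroes the entries whose
#' target state `x + shift` would leave the box (conserving truncation).
#' The table therefore defines exactly the same Markov chain as the
#' assembled generator, and is shared by [assembleGenerator()] and the
#' table-driven [gillespie()] simulator.
#'
#' @param network a [ReactionNetwork-class]
#' @param box a step-1 [LatticeBox-class]
#' @return an `N x K` matrix of rates
#' @export
propensityTable <- function(network, box) {
  stopifnot(box@step == 1L, box@d == network@d)
  states <- latticePoints(box)
  K <- length(network@channels)
  tab <- matrix(0, nrow(states), K)
  for (i in seq_len(K)) {
    ch <- network@channels[[i]]
    a <- as.numeric(ch@propensity(states))
    if (anyNA(a) || any(!is.finite(a)))
      stop(sprintf("propensity of channel %d is not finite on the box", i))
    if (any(a < 0))
      stop(sprintf("propensity of channel %d is negative on the box", i))
    tgt <- sweep(states, 2L, ch@shift, "+")
    inside <- rowSums(sweep(tgt, 2L, box@lower, "<")) == 0L &
      rowSums(sweep(tgt, 2L, box@upper, ">")) == 0L
    a[!inside] <- 0
    tab[, i] <- a
  }
  tab
}

#' @describeIn assembleGenerator sparse generator with conserving truncation
#' @export
setMethod("assembleGenerator", signature("ReactionNetwork", "LatticeBox"),
  function(network, box) {
    N <- nStates(box)
    if (N < 1L) stop("box contains no states")
    states <- latticePoints(box)
    tab <- propensityTable(network, box)
    ii <- jj <- xx <- vector("list", length(network@channels))
    for (i in seq_along(network@channels)) {
      ch <- network@channels[[i]]
      a <- tab[, i]
      nz <- which(a > 0)
      if (!length(nz)) next
      tgt <- sweep(states[nz, , drop = FALSE], 2L, ch@shift, "+")
      ii[[i]] <- stateIndex(box, tgt)
      jj[[i]] <- nz
      xx[[i]] <- a[nz]
    }
    L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(N, N))
    Matrix::diag(L) <- Matrix::diag(L) - Matrix::colSums(L)
    new("GeneratorMatrix", box = box, matrix = L, network = network@name)
  })

#' Exact lattice shift operator on a box
#'
#' Returns the sparse matrix of the operator \eqn{(T_k^n u)(x) =
#' u(x_1, \ldots, x_k - n, \ldots, x_d)} with zero fill outside the box;
#' `n = 0` gives the identity, negative `n` the adjoint-direction shift,
#' and `|n| > 1` the `n`-fold composition of unit shifts.
#'
#' @param box a step-1 [LatticeBox-class]
#' @param k axis index in `1..d`
#' @param n integer shift power
#' @return a sparse `N x N` matrix
#' @export
shiftOperatorFull <- function(box, k, n = 1L) {
  stopifnot(k >= 1L, k <= box@d)
  N <- nStates(box)
  if (n == 0L) return(Matrix::Diagonal(N))
  states <- latticePoints(box)
  # row i reads from the pre-image x with x_k decreased by n
  src <- states
  src[, k] <- src[, k] - as.integer(n)
  j <- stateIndex(box, src)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = which(keep), j = j[keep], x = 1,
                       dims = c(N, N))
}

#' Orbit structure of a box under coordinate permutations
#'
#' For a network equivariant under a group of axis permutations, the
#' stationary distribution is constant on the group orbits of the state
#' space. `permutationOrbits` enumerates those orbits; [steadyState()] can
#' then solve the (much smaller) orbit-space null problem exactly and
#' expand the result, which it always validates against the full generator.
#'
#' @param box a [LatticeBox-class] whose bounds are permutation-symmetric
#' @param perms list of permutations of `1:d` (default: all of them)
#' @return list with `id` (orbit index per state) and `size` (orbit sizes)
#' @export
permutationOrbits <- function(box, perms = NULL) {
  d <- box@d
  states <- latticePoints(box)
  if (is.null(perms)) {
    # full symmetric group: the sorted state is the canonical representative
    canon <- t(apply(states, 1L, sort))
  } else {
    # general subgroup: lexicographically smallest image is canonical
    canon <- states
    for (p in perms) {
      img <- states[, p, drop = FALSE]
      smaller <- rep(FALSE, nrow(states))
      undecided <- rep(TRUE, nrow(states))
      for (k in seq_len(d)) {
        lt <- undecided & img[, k] < canon[, k]
        gt <- undecided & img[, k] > canon[, k]
        smaller[lt] <- TRUE
        undecided[lt | gt] <- FALSE
      }
      canon[smaller, ] <- img[smaller, , drop = FALSE]
    }
  }
  key <- do.call(paste, c(lapply(seq_len(d), function(k) canon[, k]),
                          sep = ","))
  f <- factor(key, levels = unique(key))
  id <- as.integer(f)
  list(id = id, size = tabulate(id, nlevels(f)))
}

permutationsOf <- function(d) {
  if (d == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(d - 1L)
  out <- matrix(0L, 0L, d)
  for (pos in seq_len(d)) {
    ins <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], d,
                 sub[, pos:(d - 1L), drop = FALSE][, seq_len(d - pos),
                                                   drop = FALSE])
    out <- rbind(out, ins)
  }
  storage.mode(out) <- "integer"
  out
}

#' @describeIn steadyState stationary distribution of the truncated chain.
#'
#' The null vector of the sparse generator is computed by a direct sparse
#' solve: one unknown is pinned to 1, the corresponding column moved to the
#' right-hand side, and the solution renormalised to unit mass (valid
#' whenever the truncated chain has a single closed communicating class).
#' With `orbits` (from [permutationOrbits()]) the solve is performed in
#' orbit space - exact for permutation-equivariant networks and orders of
#' magnitude cheaper on 3-D boxes. In all cases the full-generator residual
#' \eqn{\|Lu\|_\infty} is computed and checked against `tol`.
#'
#' @param gen a [GeneratorMatrix-class]
#' @param orbits optional orbit structure for symmetric networks
#' @param tol residual tolerance (relative to `max(u)`)
#' @export
setMethod("steadyState", "GeneratorMatrix",
  function(gen, orbits = NULL, tol = 1e-8) {
    L <- gen@matrix
    N <- nrow(L)
    if (is.null(orbits)) {
      u <- nullVectorSparse(L)
    } else {
      M <- length(orbits$size)
      R <- Matrix::sparseMatrix(i = orbits$id, j = seq_len(N), x = 1,
                                dims = c(M, N))
      E <- Matrix::sparseMatrix(i = seq_len(N), j = orbits$id,
                                x = 1 / orbits$size[orbits$id],
                                dims = c(N, M))
      A <- R %*% L %*% E
      w <- nullVectorSparse(A)
      u <- as.numeric(E %*% w)
      u <- u / sum(u)
    }
    res <- max(abs(L %*% u)) / max(u)
    if (!is.finite(res) || res > tol)
      stop(sprintf(paste0("steady-state solve did not reach tolerance: ",
                          "relative residual %.3g > %.3g"), res, tol))
    u <- pmax(u, 0)
    u <- u / sum(u)
    out <- latticeDistribution(gen@box, u)
    attr(out, "residual") <- res
    out
  })

# direct sparse null-vector solve: pin one unknown to 1, solve for the
# rest, renormalise. A first pass (pinned at the last state) locates the
# distribution mode; the second pass pins the mode, which keeps the deep
# tail relatively accurate (no cancellation against a pinned tail state).
nullVectorSparse <- function(L) {
  N <- nrow(L)
  if (N == 1L) return(1)
  solvePinned <- function(j) {
    A <- L[-j, -j, drop = FALSE]
    rhs <- -L[-j, j, drop = FALSE]
    v <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e)
                    stop("sparse null-space solve failed: ",
                         conditionMessage(e)))
    u <- append(v, 1, after = j - 1L)
    s <- sum(u)
    if (!is.finite(s) || s <= 0)
      stop("null-space solve produced a non-normalisable vector")
    u / s
  }
  # The pinned state must carry non-negligible stationary mass: pinning a
  # deep-tail state makes every other unknown astronomically large and the
  # solve drowns in cancellation. An outflow-free (absorbing) state, if
  # present, is both the only safe pin and the location of the mass;
  # otherwise a handful of uniformization sweeps locates the mode well
  # enough to pin near it.
  absorbing <- which(Matrix::diag(L) == 0)
  j1 <- if (length(absorbing)) absorbing[1L] else {
    lam <- max(abs(Matrix::diag(L)))
    P <- Matrix::Diagonal(N) + L / lam
    v <- rep(1 / N, N)
    for (i in 1:40) v <- as.numeric(P %*% v)
    which.max(v)
  }
  u <- solvePinned(j1)
  j2 <- which.max(u)
  if (j2 == j1) return(u)
  solvePinned(j2)
}

#' @describeIn evolve transient CME solution by uniformization.
#'
#' Computes \eqn{u(t) = e^{tL} u_0} through the Poisson-weighted power
#' series of the substochastic matrix \eqn{P = I + L/\lambda} with
#' \eqn{\lambda = \max_i |L_{ii}|} (uniformization). The series is summed
#' over internally chosen substeps so that the truncation error per step is
#' below `tol`; the matrix exponential is never formed. Mass is conserved
#' to the series tolerance.
#'
#' @param gen a [GeneratorMatrix-class]
#' @param u0 a [LatticeDistribution-class] on the same box
#' @param t duration (>= 0)
#' @param tol series truncation tolerance
#' @export
setMethod("evolve", signature("GeneratorMatrix", "LatticeDistribution"),
  function(gen, u0, t, tol = 1e-10) {
    if (t < 0) stop("t must be non-negative")
    stopifnot(identical(unname(gen@box@lower), unname(u0@box@lower)),
              identical(unname(gen@box@upper), unname(u0@box@upper)))
    if (t == 0) return(u0)
    L <- gen@matrix
    lam <- max(abs(Matrix::diag(L)))
    if (lam == 0) return(u0)
    P <- Matrix::Diagonal(nrow(L)) + L / lam
    u <- u0@values
    remaining <- t
    # cap the Poisson mean per substep to keep the series short and stable
    stepT <- min(t, 500 / lam)
    while (remaining > 1e-14 * t) {
      dt <- min(stepT, remaining)
      m <- lam * dt
      K <- stats::qpois(1 - min(tol / 10, 1e-12), m) + 5
      w <- stats::dpois(0:K, m)
      acc <- w[1] * u
      v <- u
      for (k in seq_len(K)) {
        v <- as.numeric(P %*% v)
        acc <- acc + w[k + 1] * v
      }
      # compensate the (tiny) truncated Poisson tail to preserve mass
      u <- acc / sum(w)
      remaining <- remaining - dt
    }
    latticeDistribution(u0@box, u)
  })

setMethod("show", "GeneratorMatrix", function(object) {
  cat(sprintf("GeneratorMatrix (%s): %d x %d, %d non-zeros\n",
              object@network, nrow(object@matrix), ncol(object@matrix),
              Matrix::nnzero(object@matrix)))
})
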