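#' Construct a lattice box
#'
#' @param lower,upper inclusive integer bounds (recycled to a common length).
#' @param step lattice spacing; `step > 1` produces the coarse candidate grid
#'   used for basis centres and support geometry.
#' @return a [LatticeBox-class]
#' @examples
#' b <- latticeBox(c(0, 0), c(300, 300))
#' nStates(b)  # 90601
#' @export
latticeBox <- function(lower, upper, step = 1L) {
  n <- max(length(lower), length(upper))
  lower <- as.integer(rep_len(lower, n))
  upper <- as.integer(rep_len(upper, n))
  new("LatticeBox", d = as.integer(n), lower = lower, upper = upper,
      step = as.integer(step))
}

boxSizes <- function(box) (box@upper - box@lower) %/% box@step + 1L

#' @rdname nStates
#' @export
setMethod("nStates", "LatticeBox", function(box) prod(boxSizes(box)))

#' All states of a box, in enumeration order
#'
#' @param box a [LatticeBox-class]
#' @return an `N x d` integer matrix; the first axis varies fastest.
#' @export
latticePoints <- function(box) {
  sizes <- boxSizes(box)
  N <- prod(sizes)
  out <- matrix(0L, N, box@d)
  rep_each <- 1L
  for (k in seq_len(box@d)) {
    vals <- box@lower[k] + box@step * (0:(sizes[k] - 1L))
    out[, k] <- rep(rep(vals, each = rep_each), length.out = N)
    rep_each <- rep_each * sizes[k]
  }
  out
}

#' Convert states to enumeration indices and back
#'
#' `stateIndex` returns `NA` for states outside the box or off the
#' sub-lattice; the two functions are mutually inverse on valid input.
#'
#' @param box a [LatticeBox-class]
#' @param states an `m x d` matrix (or a length-`d` vector)
#' @param idx integer indices in `1..nStates(box)`
#' @return indices, respectively an `m x d` state matrix
#' @export
stateIndex <- function(box, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  sizes <- boxSizes(box)
  rel <- sweep(states, 2L, box@lower, "-")
  ok <- rowSums(rel %% box@step != 0L) == 0L
  rel <- rel %/% box@step
  ok <- ok & rowSums(rel < 0L) == 0L &
    rowSums(sweep(rel, 2L, sizes, ">=")) == 0L
  mult <- cumprod(c(1L, sizes[-box@d]))
  idx <- as.integer(rel %*% mult) + 1L
  idx[!ok] <- NA_integer_
  idx
}

#' @rdname stateIndex
#' @export
indexState <- function(box, idx) {
  sizes <- boxSizes(box)
  out <- matrix(0L, length(idx), box@d)
  rem <- as.integer(idx) - 1L
  for (k in seq_len(box@d)) {
    out[, k] <- box@lower[k] + box@step * (rem %% sizes[k])
    rem <- rem %/% sizes[k]
  }
  out
}

#' Tabulate a distribution on a box
#'
#' @param box a [LatticeBox-class]
#' @param values a numeric vector over the enumeration, a `d`-dimensional
#'   array, or a vectorised function of the state matrix.
#' @param normalize rescale to unit total mass?
#' @return a [LatticeDistribution-class]
#' @export
latticeDistribution <- function(box, values, normalize = FALSE) {
  if (is.function(values)) values <- values(latticePoints(box))
  values <- as.numeric(values)
  if (normalize) {
    m <- sum(values)
    if (m <= 0) stop("cannot normalize: total mass is not positive")
    values <- values / m
  }
  new("LatticeDistribution", box = box, values = values)
}

#' Total probability mass
#' @param u a [LatticeDistribution-class]
#' @export
latticeMass <- function(u) sum(u@values)

#' @rdname latticeBoxOf
#' @export
setMethod("latticeBoxOf", "LatticeDistribution", function(x) x@box)
#' @rdname latticeBoxOf
#' @export
setMethod("latticeBoxOf", "SupportMask", function(x) x@box)
#' @rdname latticeBoxOf
#' @export
setMethod("latticeBoxOf", "SignedDistanceField", function(x) x@box)
#' @rdname latticeBoxOf
#' @export
setMethod("latticeBoxOf", "GeneratorMatrix", function(x) x@box)

asBoxArray <- function(box, v) array(v, dim = boxSizes(box))

#' @rdname latticeValues
#' @export
setMethod("latticeValues", "LatticeDistribution", function(x, asArray = FALSE)
  if (asArray) asBoxArray(x@box, x@values) else x@values)
#' @rdname latticeValues
#' @export
setMethod("latticeValues", "SignedDistanceField", function(x, asArray = FALSE)
  if (asArray) asBoxArray(x@box, x@values) else x@values)

#' Construct a support mask
#'
#' @param box a [LatticeBox-class]
#' @param states an `m x d` matrix (or length-`d` vector) of member states,
#'   or `NULL` with `mask` given
#' @param mask a logical vector/array over the box enumeration
#' @return a [SupportMask-class]
#' @export
latticeMask <- function(box, states = NULL, mask = NULL) {
  if (is.null(mask)) {
    mask <- logical(nStates(box))
    if (!is.null(states)) {
      idx <- stateIndex(box, states)
      if (anyNA(idx)) stop("some states are outside the box")
      mask[idx] <- TRUE
    }
  }
  new("SupportMask", box = box, mask = as.logical(mask))
}

#' Logical mask of a support set
#' @param S a [SupportMask-class]
#' @param asArray reshape to a `d`-dimensional array?
#' @export
supportMask <- function(S, asArray = FALSE)
  if (asArray) asBoxArray(S@box, S@mask) else S@mask

setMethod("show", "LatticeBox", function(object) {
  cat(sprintf("LatticeBox: d=%d, [%s] .. [%s], step=%d, %d states\n",
              object@d, paste(object@lower, collapse = ","),
              paste(object@upper, collapse = ","), object@step,
              nStates(object)))
})

setMethod("show", "LatticeDistribution", function(object) {
  v <- object@values
  cat(sprintf(
    "LatticeDistribution on %d states: mass=%.6g, max=%.3g, min=%.3g\n",
    nStates(object@box), sum(v), max(v), min(v)))
})

setMethod("show", "SupportMask", function(object) {
  cat(sprintf("SupportMask: %d of %d states set\n",
              sum(object@mask), nStates(object@box)))
})

setMethod("show", "SignedDistanceField", function(object) {
  fin <- object@values[is.finite(object@values)]
  if (length(fin))
    cat(sprintf("SignedDistanceField (alpha=%g): range [%.3g, %.3g]\n",
                object@alpha, min(fin), max(fin)))
  else cat("SignedDistanceField of an empty region\n")
})
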