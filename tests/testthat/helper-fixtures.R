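# small deterministic fixtures shared across test files

bdFixture <- function(lambda = 5, mu = 1, N = 30L)
  makeFixture("birth_death", params = list(lambda = lambda, mu = mu, N = N))

# 2-species independent birth-death: product-Poisson stationary oracle
biPoissonNetwork <- function(b1 = 6, b2 = 6, d1 = 1, d2 = 1) {
  new("ReactionNetwork", d = 2L, channels = list(
    rbfCME:::channel(c(1L, 0L), function(s) rep(b1, nrow(s)), "b1"),
    rbfCME:::channel(c(-1L, 0L), function(s) d1 * s[, 1], "d1"),
    rbfCME:::channel(c(0L, 1L), function(s) rep(b2, nrow(s)), "b2"),
    rbfCME:::channel(c(0L, -1L), function(s) d2 * s[, 2], "d2")),
    name = "biPoisson", params = list(b1 = b1, b2 = b2, d1 = d1, d2 = d2),
    components = character())
}

randomMask <- function(box, pFill = 0.2) {
  latticeMask(box, mask = stats::runif(nStates(box)) < pFill)
}

# brute-force Euclidean distance to the nearest TRUE cell (all-pairs)
bruteDistance <- function(box, mask) {
  pts <- latticePoints(box)
  inside <- which(mask)
  if (!length(inside)) return(rep(Inf, nStates(box)))
  apply(pts, 1L, function(p)
    sqrt(min(colSums((t(pts[inside, , drop = FALSE]) - p)^2))))
}

# brute-force morphological closing with a Euclidean ball of radius alpha
bruteClosing <- function(box, mask, alpha) {
  dil <- bruteDistance(box, mask) <= alpha
  ero <- bruteDistance(box, !dil) > alpha
  ero | mask
}
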