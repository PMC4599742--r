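test_that("interpolation matrix degenerates correctly", {
  b1 <- makeBasis(matrix(3, 1, 1), sigma = 2)
  expect_equal(b1@A, matrix(1, 1, 1))
  far <- makeBasis(cbind(c(0, 1e4)), sigma = 1)
  expect_equal(far@A, diag(2), tolerance = 1e-12)
  expect_error(makeBasis(cbind(c(1, 1)), sigma = 1), "distinct")
})

test_that("interpolation is exact at the nodes", {
  set.seed(21)
  ctr <- as.matrix(expand.grid(0:6, 0:6))
  b <- makeBasis(ctr, sigma = 1.2)
  for (rep in 1:5) {
    v <- rnorm(49)
    cv <- interpolate(b, v)
    expect_lt(max(abs(evaluateBasis(b, cv, ctr) - v)), 1e-8 * max(abs(v)))
  }
  expect_equal(interpolate(b, numeric(49))@alpha, numeric(49))
  # nodal values of basis function 1 interpolate to the unit vector
  e1 <- interpolate(b, b@A[, 1])
  expect_equal(e1@alpha, c(1, rep(0, 48)), tolerance = 1e-9)
  expect_error(interpolate(b, numeric(5)), "one nodal value per centre")
})

test_that("evaluateBasis matches a naive per-term summation", {
  set.seed(22)
  ctr <- matrix(runif(30, 0, 10), 15, 2)
  sig <- matrix(runif(30, 0.5, 3), 15, 2)
  b <- makeBasis(ctr, sig)
  alpha <- rnorm(15)
  pts <- matrix(runif(20, 0, 10), 10, 2)
  naive <- sapply(seq_len(10), function(i) {
    s <- 0
    for (j in 1:15)
      s <- s + alpha[j] * prod(exp(-(pts[i, ] - ctr[j, ])^2 / sig[j, ]))
    s
  })
  expect_equal(evaluateBasis(b, alpha, pts), naive, tolerance = 1e-12)
  # far from every centre the expansion vanishes
  expect_lt(abs(evaluateBasis(b, alpha, c(500, 500))), 1e-30)
})

test_that("evaluateOnLattice agrees with direct evaluation", {
  set.seed(23)
  ctr <- as.matrix(expand.grid(seq(2, 18, 4), seq(2, 18, 4)))
  b <- makeBasis(ctr, sigma = 9)
  alpha <- rnorm(nrow(ctr))
  box <- latticeBox(c(0, 0), c(20, 20))
  direct <- evaluateBasis(b, alpha, latticePoints(box))
  patched <- evaluateOnLattice(b, alpha, box, cutoff = 1e-300)
  expect_equal(patched, direct, tolerance = 1e-10)
})

test_that("collocation shift acts as the lattice shift", {
  ctr <- as.matrix(expand.grid(0:8, 0:8))
  b <- makeBasis(ctr, sigma = 1.5)
  n <- nrow(ctr)
  expect_equal(approxShift(b, 1, 0), diag(n))
  # an on-grid Gaussian shifted by one grid step is exactly representable:
  # the coefficient vector is the permuted unit vector
  jFrom <- which(ctr[, 1] == 3 & ctr[, 2] == 4)
  jTo <- which(ctr[, 1] == 4 & ctr[, 2] == 4)
  e <- numeric(n); e[jFrom] <- 1
  shifted <- as.numeric(approxShift(b, 1, 1) %*% e)
  expect_lt(abs(shifted[jTo] - 1), 1e-8)
  expect_lt(max(abs(shifted[-jTo])), 1e-8)
  # general coefficients: nodal values of the shifted interpolant equal the
  # original interpolant evaluated at the displaced points
  set.seed(31)
  alpha <- rnorm(n) * exp(-rowSums((ctr - 4)^2) / 8)
  for (spec in list(c(1, 1), c(2, -1), c(1, 2))) {
    sh <- as.numeric(b@A %*% (approxShift(b, spec[1], spec[2]) %*% alpha))
    pts <- ctr; pts[, spec[1]] <- pts[, spec[1]] - spec[2]
    ref <- evaluateBasis(b, alpha, pts)
    interior <- ctr[, spec[1]] >= 2 & ctr[, spec[1]] <= 6
    expect_lt(max(abs(sh - ref)[interior]), 1e-7)
  }
})

test_that("collocation multiplication is exact at the nodes", {
  ctr <- as.matrix(expand.grid(0:5, 0:5))
  b <- makeBasis(ctr, sigma = 1.3)
  n <- nrow(ctr)
  expect_equal(approxMult(b, function(s) rep(1, nrow(s))), diag(n),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(approxMult(b, function(s) rep(2.5, nrow(s))), 2.5 * diag(n),
               tolerance = 1e-9, ignore_attr = TRUE)
  a <- function(s) 0.3 * s[, 1] + s[, 2]^2
  set.seed(33)
  alpha <- rnorm(n)
  nodal <- as.numeric(b@A %*% (approxMult(b, a) %*% alpha))
  expect_equal(nodal, a(ctr) * as.numeric(b@A %*% alpha), tolerance = 1e-8)
})

test_that("discretized generator reduces to the exact generator at nodal level", {
  fx <- bdFixture(lambda = 4, mu = 0.8, N = 24L)
  g <- assembleGenerator(fx$network, fx$box)
  b <- makeBasis(cbind(0:24), sigma = 1.0)
  Lt <- discretizeGenerator(b, fx$network)
  # nodal action A Ltilde A^-1: every interior row is exact; only the two
  # boundary rows differ (the interpolant extrapolates across the box edge
  # where the conserving truncation of the exact generator zero-fills),
  # and that defect decays geometrically into the interior
  nodalOp <- b@A %*% Lt@matrix %*% b@Ainv
  D <- abs(as.matrix(nodalOp - g@matrix))
  expect_lt(max(D[2:24, ]), 1e-12)
  expect_lt(max(D[c(1, 25), 10:16]), 1e-3)
  expect_lt(max(D[1, 10:16]), 1e-2 * max(D[1, 1:3]))
  # all-zero propensities give the zero operator
  net0 <- new("ReactionNetwork", d = 1L, channels = list(
    rbfCME:::channel(1L, function(s) rep(0, nrow(s)), "null")),
    name = "null", params = list(), components = character())
  expect_equal(discretizeGenerator(b, net0)@matrix, matrix(0, 25, 25))
  # a single-channel network equals its single term
  net1 <- new("ReactionNetwork", d = 1L, channels = fx$network@channels[1],
              name = "birth_only", params = list(), components = character())
  W <- approxMult(b, fx$network@channels[[1]]@propensity)
  S <- approxShift(b, 1, 1)
  expect_equal(discretizeGenerator(b, net1)@matrix,
               unname(as.matrix(S %*% W - W)), tolerance = 1e-12)
})

test_that("collocation stepping matches the exact evolution on a full basis", {
  fx <- bdFixture(lambda = 4, mu = 0.8, N = 34L)
  g <- assembleGenerator(fx$network, fx$box)
  b <- makeBasis(cbind(0:34), sigma = 1.0)
  Lt <- discretizeGenerator(b, fx$network)
  # interior-supported initial condition: away from the box edges the
  # boundary conventions of the two schemes cannot differ
  u0 <- exp(-(0:34 - 17)^2 / 8); u0 <- u0 / sum(u0)
  a0 <- interpolate(b, u0)
  expect_identical(collocationStep(Lt, a0, 0)@alpha, a0@alpha)
  a1 <- collocationStep(Lt, a0, 2)
  nodal <- as.numeric(b@A %*% a1@alpha)
  exact <- evolve(g, latticeDistribution(fx$box, u0), 2)@values
  expect_lt(max(abs(nodal - exact)[4:32]), 1e-6)
  expect_lt(max(abs(nodal - exact)), 1e-4)
  # semigroup property in coefficient space
  a2a <- collocationStep(Lt, a1, 3)
  a2b <- collocationStep(Lt, a0, 5)
  expect_lt(max(abs(a2a@alpha - a2b@alpha)), 1e-8)
  expect_error(collocationStep(Lt, a0, -1), "non-negative")
})

test_that("conditioning grows monotonically with sigma on a fixed grid", {
  ctr <- as.matrix(expand.grid(0:7, 0:7))
  kappas <- sapply(c(0.6, 1.2, 2.4), function(s)
    makeBasis(ctr, sigma = s, conditionCap = 1e16)@kappa)
  expect_true(all(diff(kappas) > 0))
})

test_that("an over-saturated basis is refused with actionable advice", {
  ctr <- as.matrix(expand.grid(0:9, 0:9))
  expect_error(makeBasis(ctr, sigma = 60, conditionCap = 1e8),
               "decrease sigma|ill-conditioned")
})
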