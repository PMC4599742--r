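test_that("essential support thresholds behave as set operations", {
  box <- latticeBox(c(0, 0), c(10, 10))
  u <- latticeDistribution(box, function(s)
    exp(-((s[, 1] - 5)^2 + (s[, 2] - 5)^2) / 4), normalize = TRUE)
  expect_equal(essentialSupport(u, 0)@mask, u@values > 0)
  expect_false(any(essentialSupport(u, max(u@values) * 1.01)@mask))
  S <- essentialSupport(u, 1e-3)
  expect_identical(S@mask, u@values > 1e-3)
  expect_error(essentialSupport(u, -1), "non-negative")
})

test_that("distance transform matches the brute-force all-pairs oracle", {
  set.seed(51)
  boxes <- list(latticeBox(0, 25), latticeBox(c(0, 0), c(12, 9)),
                latticeBox(c(0, 0, 0), c(6, 5, 4)))
  for (box in boxes) {
    for (rep in 1:3) {
      m <- randomMask(box, 0.15)
      mine <- rbfCME:::distanceToSet(box, m@mask)
      expect_equal(mine, bruteDistance(box, m@mask), tolerance = 1e-12)
    }
  }
})

test_that("alpha regions reproduce closing behaviour", {
  box <- latticeBox(c(0, 0), c(40, 40))
  # single point stays a single point
  S1 <- latticeMask(box, c(20, 20))
  expect_identical(alphaRegion(S1, 2)@mask, S1@mask)
  # two clusters farther apart than 2*alpha stay disjoint
  S2 <- latticeMask(box, rbind(c(5, 5), c(30, 30)))
  expect_equal(connectedComponents(alphaRegion(S2, 2))$count, 2L)
  # a ring keeps its hole for small alpha and fills it for large alpha
  pts <- latticePoints(box)
  r <- sqrt((pts[, 1] - 20)^2 + (pts[, 2] - 20)^2)
  ring <- latticeMask(box, mask = r >= 8 & r <= 11)
  inner <- r < 6
  expect_true(any(!alphaRegion(ring, 2)@mask[inner]))
  expect_false(any(!alphaRegion(ring, 12)@mask[inner]))
  expect_error(alphaRegion(ring, 0.5), "at least one grid step")
  # empty input stays empty
  expect_false(any(alphaRegion(latticeMask(box), 2)@mask))
})

test_that("alpha regions match a brute-force closing oracle on random masks", {
  set.seed(52)
  box2 <- latticeBox(c(0, 0), c(11, 10))
  box3 <- latticeBox(c(0, 0, 0), c(6, 6, 5))
  for (case in list(list(box2, 2), list(box2, 3.5), list(box3, 2))) {
    for (rep in 1:3) {
      m <- randomMask(case[[1]], 0.12)
      expect_identical(alphaRegion(m, case[[2]])@mask,
                       bruteClosing(case[[1]], m@mask, case[[2]]))
    }
  }
})

test_that("signed distance fields invert exactly on the lattice", {
  set.seed(53)
  box <- latticeBox(c(0, 0), c(15, 15))
  for (rep in 1:6) {
    m <- randomMask(box, 0.1)
    if (!any(m@mask)) next
    d <- signedDistance(m, 2)
    expect_identical(sublevelSet(d, 0)@mask, alphaRegion(m, 2)@mask)
  }
  # full-box region: everywhere inside
  full <- latticeMask(box, mask = rep(TRUE, nStates(box)))
  expect_true(all(signedDistance(full, 2)@values <= 0))
  # single interior point: outside values are Euclidean distances
  S <- latticeMask(box, c(7, 7))
  d <- signedDistance(S, 2)
  pts <- latticePoints(box)
  out <- !alphaRegion(S, 2)@mask
  expect_equal(d@values[out],
               sqrt((pts[out, 1] - 7)^2 + (pts[out, 2] - 7)^2))
})

test_that("sublevel sets grow monotonically with the level", {
  box <- latticeBox(c(0, 0), c(20, 20))
  d <- signedDistance(latticeMask(box, rbind(c(5, 9), c(12, 4))), 2)
  prev <- NULL
  for (lev in c(-Inf, -1, 0, 1.5, 3, 8)) {
    cur <- sublevelSet(d, lev)@mask
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_false(any(sublevelSet(d, -Inf)@mask))
})

test_that("union of signed distance fields represents the union of regions", {
  box <- latticeBox(c(0, 0), c(30, 30))
  S1 <- latticeMask(box, rbind(c(6, 6), c(7, 6)))
  S2 <- latticeMask(box, rbind(c(22, 22), c(22, 23)))
  d1 <- signedDistance(S1, 2); d2 <- signedDistance(S2, 2)
  dU <- unionRegions(d1, d2)
  expect_identical(dU@values, pmin(d1@values, d2@values))
  un <- sublevelSet(dU, 0)@mask
  expect_true(all(un[sublevelSet(d1, 0)@mask]))
  expect_true(all(un[sublevelSet(d2, 0)@mask]))
  expect_equal(connectedComponents(sublevelSet(dU, 0))$count, 2L)
  # far-separated blobs: min-combination equals the recomputed union field
  direct <- signedDistance(latticeMask(box, mask = S1@mask | S2@mask), 2)
  expect_equal(dU@values, direct@values, tolerance = 1e-12)
  expect_identical(unionRegions(d1, d1)@values, d1@values)
})

test_that("support extrapolation is exact for a translating half-plane", {
  box <- latticeBox(c(0, 0), c(30, 12))
  pts <- latticePoints(box)
  plane <- function(edge) latticeMask(box, mask = pts[, 1] <= edge)
  Sp <- extrapolateSupport(plane(8), plane(10), 0, 2, 3)
  expect_identical(Sp@mask, plane(11)@mask)
  # doubling the look-ahead doubles the displacement
  Sp2 <- extrapolateSupport(plane(8), plane(10), 0, 2, 4)
  expect_identical(Sp2@mask, plane(12)@mask)
  # a static support stays put
  expect_identical(extrapolateSupport(plane(9), plane(9), 0, 1, 2)@mask,
                   plane(9)@mask)
  expect_error(extrapolateSupport(plane(8), plane(9), 1, 1, 2), "times")
})

test_that("support extrapolation tracks a translating disc to within one cell", {
  fx <- makeFixture("translating_mask",
                    params = list(steps = 3L, radius = 4, speed = 1))
  Sp <- extrapolateSupport(fx$masks[[1]], fx$masks[[2]], 0, 1, 2)
  truth <- fx$masks[[3]]
  # Hausdorff distance between prediction and truth at most one cell
  dPred <- rbfCME:::distanceToSet(fx$box, Sp@mask)
  dTrue <- rbfCME:::distanceToSet(fx$box, truth@mask)
  expect_lte(max(dPred[truth@mask]), 1)
  expect_lte(max(dTrue[Sp@mask]), 1)
})

test_that("support discrepancy is a symmetric boundary-displacement measure", {
  box <- latticeBox(c(0, 0), c(25, 25))
  pts <- latticePoints(box)
  disc <- function(r) latticeMask(box, mask =
    (pts[, 1] - 12)^2 + (pts[, 2] - 12)^2 <= r^2)
  A <- disc(5); B <- disc(6)
  expect_equal(supportDiscrepancy(A, A), 0)
  dAB <- supportDiscrepancy(A, B)
  expect_gte(dAB, 0.9); expect_lte(dAB, 2)
  expect_equal(dAB, supportDiscrepancy(B, A))
  expect_equal(supportDiscrepancy(latticeMask(box), latticeMask(box)), 0)
  expect_equal(supportDiscrepancy(A, latticeMask(box)), Inf)
})

test_that("connected components use face connectivity", {
  box <- latticeBox(c(0, 0), c(10, 10))
  expect_equal(connectedComponents(latticeMask(box))$count, 0L)
  two <- latticeMask(box, rbind(c(1, 1), c(1, 2), c(8, 8)))
  cc <- connectedComponents(two)
  expect_equal(cc$count, 2L)
  expect_equal(cc$labels[stateIndex(box, c(1, 1))],
               cc$labels[stateIndex(box, c(1, 2))])
  # diagonal neighbours are NOT connected under the face convention
  diag2 <- latticeMask(box, rbind(c(4, 4), c(5, 5)))
  expect_equal(connectedComponents(diag2)$count, 2L)
  # 3-D case
  box3 <- latticeBox(c(0, 0, 0), c(5, 5, 5))
  blobs <- latticeMask(box3, rbind(c(0, 0, 0), c(0, 0, 1), c(4, 4, 4)))
  expect_equal(connectedComponents(blobs)$count, 2L)
})
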