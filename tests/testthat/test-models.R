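test_that("toggle switch propensities match the defining Hill forms", {
  net <- buildToggle2d()
  expect_equal(net@d, 2L)
  expect_length(net@channels, 4L)
  expect_equal(lapply(net@channels, slot, "shift"),
               list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
  a <- propensities(net, c(0, 0))
  expect_equal(a[1], 3e3 / 1.1e4)
  expect_equal(a[2], 0)
  a2 <- propensities(net, c(100, 100))
  expect_equal(a2[1], 3000 / (11000 + 100^2))
  expect_equal(a2[1], 3000 / 21000)
  # independent re-evaluation on random states
  set.seed(5)
  st <- cbind(sample(0:300, 40, TRUE), sample(0:300, 40, TRUE))
  a <- propensities(net, st)
  expect_equal(a[, 1], 3000 / (11000 + st[, 2]^2))
  expect_equal(a[, 2], 1e-3 * st[, 1])
  expect_equal(a[, 3], 3000 / (11000 + st[, 1]^2))
  expect_equal(a[, 4], 1e-3 * st[, 2])
})

test_that("degradation vanishes at zero copy number", {
  net <- buildToggle2d()
  st <- cbind(0, sample(0:300, 20, TRUE))
  expect_true(all(propensities(net, st)[, 2] == 0))
})

test_that("invalid toggle parameters are rejected", {
  expect_error(toggleParams(c1 = -1), "positive")
  expect_error(toggleParams(beta = 0.5), "exponent")
  expect_error(buildToggle2d(tristableParams()), "2-species")
})

test_that("tristable network is permutation-equivariant and matches Eq-form", {
  for (params in list(tristableParams(), tristableParamsReduced())) {
    net <- buildTristable3d(params)
    expect_length(net@channels, 6L)
    r <- params@rates
    st <- c(50, 20, 10)
    a <- propensities(net, st)
    expect_equal(as.numeric(a),
                 c(r[["c1"]] / (r[["c2"]] + (20 + 10)^2), r[["c3"]] * 50,
                   r[["c4"]] / (r[["c5"]] + (50 + 10)^2), r[["c6"]] * 20,
                   r[["c7"]] / (r[["c8"]] + (50 + 20)^2), r[["c9"]] * 10))
    expect_equal(as.numeric(propensities(net, c(0, 0, 0))[c(2, 4, 6)]),
                 c(0, 0, 0))
    set.seed(7)
    st <- cbind(sample(0:120, 100, TRUE), sample(0:120, 100, TRUE),
                sample(0:120, 100, TRUE))
    a <- propensities(net, st)
    perms <- list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2), c(2, 3, 1), c(3, 1, 2))
    for (p in perms) {
      ap <- propensities(net, st[, p, drop = FALSE])
      # channel block for species k under permutation p comes from block p[k]
      reorder <- as.vector(rbind(2 * p - 1, 2 * p))
      expect_equal(ap, a[, reorder], tolerance = 1e-12)
    }
  }
})

test_that("OCS propensities reproduce the published parameter table", {
  net <- buildOcs()
  a <- propensities(net, c(0, 0, 0))
  expect_equal(a[1], 1 / 1)      # b_o / m_o
  expect_equal(a[5], 0.5 / 10)   # b_p / m_p
  expect_equal(a[3], 1 / 1)
  aStim <- propensities(buildOcs(ocsParams(zo = 6)), c(0, 0, 0))
  expect_equal(aStim[1], (1 + 6) / 1)
  expect_equal(aStim[-1], a[-1])
  # mp enters only the progenitor production channel
  set.seed(3)
  st <- cbind(sample(0:40, 25), sample(0:40, 25), sample(0:40, 25))
  a8 <- propensities(buildOcs(ocsParams(mp = 8)), st)
  a10 <- propensities(buildOcs(ocsParams(mp = 10)), st)
  expect_equal(a8[, -5], a10[, -5])
  expect_false(any(a8[st[, 3] > 0, 5] == a10[st[, 3] > 0, 5]))
})

test_that("OCS without stimulus is equivariant under osteo/chondro swap", {
  net <- buildOcs()
  set.seed(9)
  st <- cbind(sample(0:50, 60, TRUE), sample(0:50, 60, TRUE),
              sample(0:50, 60, TRUE))
  a <- propensities(net, st)
  aSwap <- propensities(net, st[, c(2, 1, 3)])
  expect_equal(aSwap[, c(3, 4, 1, 2, 5, 6)], a, tolerance = 1e-12)
})

test_that("gene-model binding rates follow the declared stoichiometry", {
  pm <- geneModelParams(h = 0.4, bindingMode = "monomer")
  netM <- buildSelfRegulatingGene(pm)
  # binding channel is the on->off switch (third channel)
  expect_equal(propensities(netM, c(3, 0))[3], 3 * 0.4)
  netD <- buildSelfRegulatingGene(geneModelParams(h = 0.4,
                                                  bindingMode = "dimer"))
  expect_equal(propensities(netD, c(1, 0))[3], 0)
  expect_equal(propensities(netD, c(4, 0))[3], 0.4 / 2 * 4 * 3)
  expect_error(geneModelParams(bindingMode = "trimer"), "monomer")
  sc <- geneModelScales(geneModelParams(gOn = 20, gOff = 4, k = 2, f = 3,
                                        h = 0.5))
  expect_equal(unname(sc), c((20 + 4) / 4, 3 / 0.5, 3 / 2))
})

test_that("gene-model master operator conserves probability and keeps (0,off) unreachable", {
  net <- buildSelfRegulatingGene(geneModelParams(gOn = 10, gOff = 2, k = 1,
                                                 f = 0.5, h = 0.05))
  box <- latticeBox(c(0, 0), c(40, 1))
  g <- assembleGenerator(net, box)
  expect_lt(max(abs(Matrix::colSums(g@matrix))), 1e-12)
  iDead <- stateIndex(box, c(0, 1))
  # no transition feeds the non-physical (0, off) state
  expect_equal(sum(abs(g@matrix[iDead, -iDead])), 0)
  u <- steadyState(g)
  expect_equal(u@values[iDead], 0)
})

test_that("gene expression peaks fuse as switching becomes fast", {
  box <- latticeBox(c(0, 0), c(55, 1))
  overall <- function(f, h) {
    net <- buildSelfRegulatingGene(geneModelParams(gOn = 25, gOff = 3,
                                                   k = 1, f = f, h = h))
    u <- steadyState(assembleGenerator(net, box))
    rowSums(matrix(u@values, 56, 2))
  }
  nModes <- function(tot) {
    lm <- which(diff(sign(diff(tot))) == -2) + 1
    length(lm[tot[lm] > 1e-4])
  }
  expect_equal(nModes(overall(f = 0.05, h = 0.002)), 2) # slow: bimodal
  expect_equal(nModes(overall(f = 5, h = 0.2)), 1)      # fast: fused
})

test_that("built-in propensities are non-negative on their boxes", {
  cases <- list(
    list(buildToggle2d(), latticeBox(c(0, 0), c(300, 300))),
    list(buildTristable3d(tristableParamsReduced()),
         latticeBox(c(0, 0, 0), c(45, 45, 45))),
    list(buildOcs(), latticeBox(c(0, 0, 0), c(30, 30, 30))),
    list(buildSelfRegulatingGene(), latticeBox(c(0, 0), c(60, 1))))
  for (cs in cases) {
    tab <- propensityTable(cs[[1]], cs[[2]])
    expect_true(all(is.finite(tab)) && all(tab >= 0),
                label = cs[[1]]@name)
  }
})

test_that("OCS stationary landscape has the three fate modes, progenitor-dominant at mp = 8", {
  box <- latticeBox(c(0, 0, 0), c(24, 24, 24))
  orb <- permutationOrbits(box, perms = list(c(2, 1, 3)))
  maxima <- function(mp) {
    u <- steadyState(assembleGenerator(buildOcs(ocsParams(mp = mp)), box),
                     orbits = orb)
    ua <- latticeValues(u, asArray = TRUE)
    lm <- NULL
    for (i in 1:25) for (j in 1:25) for (k in 1:25) {
      nb <- ua[max(1, i - 1):min(25, i + 1), max(1, j - 1):min(25, j + 1),
               max(1, k - 1):min(25, k + 1)]
      if (ua[i, j, k] > 1e-5 && ua[i, j, k] >= max(nb) &&
          sum(nb == ua[i, j, k]) == 1)
        lm <- rbind(lm, c(i - 1, j - 1, k - 1, ua[i, j, k]))
    }
    lm
  }
  for (mp in c(10, 8)) {
    lm <- maxima(mp)
    expect_equal(nrow(lm), 3L)
    # a progenitor mode on the z-axis and an osteo/chondro pair mirrored in x<->y
    prog <- lm[lm[, 1] == 0 & lm[, 2] == 0, , drop = FALSE]
    expect_equal(nrow(prog), 1L)
    expect_gt(prog[1, 3], 8)
    oc <- lm[!(lm[, 1] == 0 & lm[, 2] == 0), , drop = FALSE]
    expect_equal(oc[1, c(2, 1, 3, 4)], oc[2, ], tolerance = 1e-10)
    if (mp == 10) pWeak <- prog[1, 4] / max(oc[, 4])
    if (mp == 8) pStrong <- prog[1, 4] / max(oc[, 4])
  }
  # lowering the progenitor inflection point stabilises the progenitor state
  expect_lt(pWeak, 1)
  expect_gt(pStrong, 1)
})
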