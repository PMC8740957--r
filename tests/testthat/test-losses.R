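test_that("Gaussian kernels match the closed-form taps", {
  k0 <- gaussianKernel(0)
  expect_identical(k0@taps, 1)
  expect_identical(k0@offsets, 0L)

  k1 <- gaussianKernel(1)
  expect_length(k1@taps, 7L)                       # 6 sigma + 1 taps
  expect_lt(abs(sum(k1@taps) - 1), 1e-12)
  # oracle: evaluate exp(-x^2/2 sigma^2) at x = -3..3 and normalize
  raw <- exp(-(-3:3)^2 / 2)
  expect_equal(k1@taps, raw / sum(raw), tolerance = 1e-14)

  for (s in c(1, 2, 4, 8)) {
    k <- gaussianKernel(s)
    expect_length(k@taps, 6L * s + 1L)
    expect_lt(abs(sum(k@taps) - 1), 1e-12)
    expect_equal(k@taps, rev(k@taps))              # even function
  }
  expect_error(gaussianKernel(-1), "non-negative")
  expect_error(gaussianKernel(1.5), "integer")
})

test_that("label smoothing is a separable zero-extension convolution", {
  set.seed(21)
  a <- array(runif(6 * 5 * 4), c(6, 5, 4))
  expect_identical(smoothLabel(a, gaussianKernel(0)), a)  # identity kernel

  k <- gaussianKernel(1)
  expect_equal(smoothLabel(a, k), naiveSmooth3(a, k@taps), tolerance = 1e-12)

  # interior of an all-ones block stays 1 under a unit-sum kernel
  ones <- array(1, c(13, 13, 13))
  sm <- smoothLabel(ones, k)
  expect_lt(max(abs(sm[7, 7, 7] - 1)), 1e-9)

  # single voxel: centre value is the product of the three axis centre taps
  spike <- array(0, c(9, 9, 9)); spike[5, 5, 5] <- 1
  sm <- smoothLabel(spike, k)
  expect_equal(sm[5, 5, 5], k@taps[4]^3, tolerance = 1e-12)

  # mass conserved exactly when support stays 3 sigma from every boundary
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("soft Dice matches hand-counted overlaps", {
  g <- array(0, c(4, 4, 4)); g[1:3, 1, 1] <- 1
  p <- array(0, c(4, 4, 4)); p[2:4, 1, 1] <- 1       # 3 vs 3, overlap 2
  expect_equal(dscLoss(p, g), 1 - 4 / (6 + 1e-6), tolerance = 1e-9)
  expect_equal(dscLoss(p, g, epsilon = 0), 1 / 3, tolerance = 1e-12)

  expect_lt(dscLoss(g, g), 1e-6)                     # perfect overlap
  q <- array(0, c(4, 4, 4)); q[1, 4, 4] <- 1
  expect_gt(dscLoss(q, g), 1 - 1e-6)                 # disjoint
  expect_error(dscLoss(array(0, c(3, 3, 3)), g), "extents differ")
})

test_that("the analytic Dice gradient reproduces the closed form", {
  # single-entry labels make the closed form 2 g^2/(p+g)^2 exact
  for (pv in c(0.01, 0.3, 1)) for (gv in c(0.2, 1)) {
    p <- array(0, c(3, 3, 3)); p[2, 2, 2] <- pv
    g <- array(0, c(3, 3, 3)); g[2, 2, 2] <- gv
    got <- dscLoss(p, g, epsilon = 0, gradient = TRUE)$gradient[2, 2, 2]
    expect_equal(abs(got), diceGradientOracle(pv, gv), tolerance = 1e-10)
  }
  expect_equal(diceGradientOracle(1, 1), 0.5)
  expect_equal(diceGradientOracle(0.5, 0), 0)
  expect_equal(diceGradientOracle(0.01, 1), 2 / 1.01^2)
  # the blow-up the smoothing addresses: gradient grows as p+g shrinks
  expect_gt(diceGradientOracle(0.001, 0.01), diceGradientOracle(0.1, 1))
  expect_error(diceGradientOracle(0, 0), "positive")
})

test_that("dscLoss gradient matches finite differences on random labels", {
  set.seed(22)
  p <- randLabel(c(5, 5, 5), density = 0.3)
  g <- randLabel(c(5, 5, 5), density = 0.3)
  gr <- dscLoss(p, g, gradient = TRUE)$gradient
  eps <- 1e-6
  for (i in sample(125, 5)) {
    pp <- p; pp[i] <- pp[i] + eps; up <- dscLoss(pp, g)
    pp[i] <- pp[i] - 2 * eps; dn <- dscLoss(pp, g)
    expect_equal(gr[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("GDSC with sigma {0} collapses to plain Dice", {
  set.seed(23)
  for (i in 1:5) {
    p <- randLabel(c(6, 6, 6), density = 0.2)
    g <- randLabel(c(6, 6, 6), density = 0.2)
    expect_lt(abs(gdscLoss(p, g, sigmaSet = 0) - dscLoss(p, g)), 1e-9)
  }
  expect_error(gdscLoss(p, g, sigmaSet = numeric(0)), "at least one")
})

test_that("GDSC rewards near-misses that plain Dice cannot see", {
  # disjoint single voxels two apart: sharp Dice saturates at 1, the
  # smoothed scale overlaps their tails
  p <- array(0, c(9, 9, 9)); p[4, 5, 5] <- 1
  g <- array(0, c(9, 9, 9)); g[6, 5, 5] <- 1
  l01 <- gdscLoss(p, g, sigmaSet = c(0, 1))
  expect_lt(l01, 1)
  expect_gt(dscLoss(p, g), 1 - 1e-6)
  # oracle for the two-scale value: mean of per-scale overlaps
  k <- gaussianKernel(1)
  ps <- naiveSmooth3(p, k@taps); gs <- naiveSmooth3(g, k@taps)
  ov1 <- 2 * sum(ps * gs) / (sum(ps) + sum(gs) + 1e-6)
  ov0 <- 2 * sum(p * g) / (sum(p) + sum(g) + 1e-6)
  expect_equal(l01, 1 - (ov0 + ov1) / 2, tolerance = 1e-9)
})

test_that("GDSC gradient matches finite differences", {
  set.seed(24)
  p <- randLabel(c(7, 7, 7), density = 0.2)
  g <- randLabel(c(7, 7, 7), density = 0.2)
  gr <- gdscLoss(p, g, sigmaSet = c(0, 1, 2), gradient = TRUE)$gradient
  eps <- 1e-6
  for (i in sample(343, 5)) {
    pp <- p; pp[i] <- pp[i] + eps
    up <- gdscLoss(pp, g, sigmaSet = c(0, 1, 2))
    pp[i] <- pp[i] - 2 * eps
    dn <- gdscLoss(pp, g, sigmaSet = c(0, 1, 2))
    expect_equal(gr[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("smoothness penalties behave like their differential forms", {
  ext <- c(6, 6, 6)
  # constant field: zero first-order penalty
  u <- array(0, c(ext, 3)); u[, , , 1] <- 2.5
  expect_identical(smoothnessLoss(u, "gradient"), 0)
  expect_identical(smoothnessLoss(identityDvf(ext)), 0)

  # linear (uniform scaling) field: zero bending, positive gradient penalty
  lin <- array(0, c(ext, 3))
  lin[, , , 1] <- 0.3 * (row(matrix(0, ext[1], ext[2]))[, 1] - 1)
  expect_gt(smoothnessLoss(lin, "gradient"), 0)
  expect_lt(smoothnessLoss(lin, "bending"), 1e-12)

  # single spike: hand-computed forward differences around it -- the spike
  # voxel carries diffs of -m on all three axes (norm m*sqrt(3)), each of
  # its three lower neighbours carries one diff of +m (norm m)
  sp <- array(0, c(ext, 3)); m <- 2
  sp[3, 3, 3, 1] <- m
  expect_equal(smoothnessLoss(sp, "gradient"),
               (sqrt(3) + 3) * m / prod(ext), tolerance = 1e-12)
  expect_error(smoothnessLoss(u, "diffusion"))
})

test_that("smoothness gradients match finite differences", {
  set.seed(25)
  u <- array(rnorm(4 * 4 * 4 * 3, sd = 0.5), c(4, 4, 4, 3))
  for (variant in c("gradient", "bending")) {
    gr <- smoothnessLoss(u, variant, gradient = TRUE)
    expect_equal(gr$value, smoothnessLoss(u, variant), tolerance = 1e-12)
    eps <- 1e-6
    for (i in sample(length(u), 5)) {
      uu <- u; uu[i] <- uu[i] + eps; up <- smoothnessLoss(uu, variant)
      uu[i] <- uu[i] - 2 * eps; dn <- smoothnessLoss(uu, variant)
      expect_equal(gr$gradient[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("the combined objective is the weighted sum of its parts", {
  set.seed(26)
  p <- randLabel(c(6, 6, 6), density = 0.2)
  g <- randLabel(c(6, 6, 6), density = 0.2)
  u <- array(rnorm(6 * 6 * 6 * 3, sd = 0.2), c(6, 6, 6, 3))
  tl <- totalLoss(p, g, u, alpha = 0.5, sigmaSet = c(0, 1))
  expect_equal(tl$value, tl$gdsc + 0.5 * tl$smooth, tolerance = 1e-12)
  expect_equal(totalLoss(p, g, u, alpha = 0, sigmaSet = c(0, 1))$value,
               gdscLoss(p, g, sigmaSet = c(0, 1)), tolerance = 1e-12)
  # zero field, identical binary labels, sharp scale only: total 0
  b <- (randLabel(c(6, 6, 6), density = 0.2, soft = FALSE) > 0) * 1
  z <- array(0, c(6, 6, 6, 3))
  expect_lt(totalLoss(b, b, z, alpha = 0.5, sigmaSet = 0)$value, 1e-6)
  expect_equal(0.4 + 0.5 * 0.2, 0.5)  # the linear combination arithmetic
})

test_that("losses stay within their theoretical bounds", {
  set.seed(27)
  for (i in 1:10) {
    p <- randLabel(c(6, 6, 6), density = runif(1, 0.05, 0.5))
    g <- randLabel(c(6, 6, 6), density = runif(1, 0.05, 0.5))
    d <- dscLoss(p, g)
    gd <- gdscLoss(p, g, sigmaSet = c(0, 1, 2))
    expect_gte(d, 0); expect_lte(d, 1 + 1e-9)
    expect_gte(gd, 0); expect_lte(gd, 1 + 1e-9)
  }
})
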