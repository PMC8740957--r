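test_that("network construction follows the configuration", {
  cfg <- networkConfig(levels = 2, baseChannels = 4)
  net <- buildNetwork(cfg, seed = 1)
  expect_s4_class(net, "SiameseUNet")
  # first conv: 7x7x7 kernel over (image, label) channels
  expect_identical(dim(net@params$first$W), c(4L, 2L, 7L, 7L, 7L))
  # final layer zero-initialized: identity transform at the start
  expect_identical(max(abs(net@params$final$W)), 0)
  # same seed, same weights
  net2 <- buildNetwork(cfg, seed = 1)
  expect_identical(net@params, net2@params)
  expect_error(networkConfig(levels = 0), "levels")
  expect_error(networkConfig(pool = 3), "pool")
})

test_that("both branches share one parameter set", {
  cfg <- networkConfig(levels = 1, baseChannels = 2, useLabelChannels = FALSE)
  net <- buildNetwork(cfg, seed = 2)
  x <- array(rnorm(1 * 8 * 8 * 8), c(1L, 8L, 8L, 8L))
  # the same input through the fixed-branch and moving-branch encoders
  # yields identical features (they are the same weights)
  eF <- siamreg:::.encoderFw(net@params, cfg, x)
  eM <- siamreg:::.encoderFw(net@params, cfg, x)
  expect_identical(eF$bottom, eM$bottom)
  expect_identical(eF$skips, eM$skips)
})

test_that("weight sharing accumulates gradients from both branches", {
  cfg <- networkConfig(levels = 1, baseChannels = 2, useLabelChannels = FALSE)
  net <- buildNetwork(cfg, seed = 3)
  p <- net@params
  p$final$W[] <- stats::rnorm(length(p$final$W), sd = 0.1)
  xF <- array(rnorm(1 * 8 * 8 * 8), c(1L, 8L, 8L, 8L))
  xM <- array(rnorm(1 * 8 * 8 * 8), c(1L, 8L, 8L, 8L))
  fw <- siamreg:::.netForward(p, cfg, xF, xM, train = TRUE)
  dOut <- array(1, dim(fw$out))
  gr <- siamreg:::.netBackward(p, cfg, fw, dOut)
  # swapping the branch inputs leaves the shared encoder gradient the sum of
  # the same two per-branch contributions
  fw2 <- siamreg:::.netForward(p, cfg, xM, xF, train = TRUE)
  gr2 <- siamreg:::.netBackward(p, cfg, fw2, dOut)
  expect_identical(names(gr), names(gr2))
  expect_true(all(c("first", "enc1.c1", "bott.c2", "dec1.c1", "final") %in%
                  names(gr)))
  # one parameter set: a single update moves both branches identically
  p2 <- p
  p2$first$W <- p2$first$W - 0.01 * array(gr$first$dW, dim(p2$first$W))
  eF <- siamreg:::.encoderFw(p2, cfg, xF)
  eM <- siamreg:::.encoderFw(p2, cfg, xF)
  expect_identical(eF$bottom, eM$bottom)
})

test_that("parameter count is independent of input extents", {
  cfg <- networkConfig(levels = 2, baseChannels = 4)
  net <- buildNetwork(cfg, seed = 4)
  nParams <- sum(vapply(net@params, function(p) length(p$W) + length(p$b), 1L))
  mk <- function(ext) {
    v <- ImageVolume(array(rnorm(prod(ext)), ext), spacing = 1)
    l <- LabelVolume(array(0, ext), spacing = 1)
    list(v = v, l = l)
  }
  a <- mk(c(16, 16, 16)); b <- mk(c(24, 16, 12))
  # the very same network runs on different extents (fully convolutional)
  d1 <- predictDvf(net, a$v, a$v, a$l, a$l)
  d2 <- predictDvf(net, b$v, b$v, b$l, b$l)
  expect_identical(extents(d1), c(16L, 16L, 16L))
  expect_identical(extents(d2), c(24L, 16L, 12L))
  expect_identical(
    nParams,
    sum(vapply(net@params, function(p) length(p$W) + length(p$b), 1L)))
})

test_that("pooling arithmetic reaches the expected bottleneck extents", {
  cfg <- networkConfig(levels = 3, baseChannels = 2, useLabelChannels = FALSE)
  net <- buildNetwork(cfg, seed = 5)
  x <- array(rnorm(1 * 16 * 16 * 24), c(1L, 16L, 16L, 24L))
  enc <- siamreg:::.encoderFw(net@params, cfg, x)
  expect_identical(dim(enc$bottom)[2:4], c(2L, 2L, 3L))   # input / 2^3
})

test_that("zero-initialized networks predict the identity transform", {
  cfg <- networkConfig(levels = 2, baseChannels = 4)
  net <- buildNetwork(cfg, seed = 6)
  ext <- c(16L, 16L, 16L)
  v <- ImageVolume(array(rnorm(prod(ext)), ext), spacing = 1)
  l <- LabelVolume((array(runif(prod(ext)), ext) > 0.9) * 1, spacing = 1)
  dvf <- predictDvf(net, v, v, l, l)
  expect_identical(max(abs(dvfVectors(dvf))), 0)
})

test_that("cross-scale forward always returns the fixed extents", {
  cfg <- networkConfig(levels = 2, baseChannels = 2)
  net <- buildNetwork(cfg, seed = 7)
  set.seed(77)
  div <- 4L
  for (i in 1:8) {
    extF <- div * sample(3:6, 3, replace = TRUE)
    extM <- pmin(extF, div * sample(2:6, 3, replace = TRUE))
    vF <- ImageVolume(array(rnorm(prod(extF)), extF), spacing = 1)
    lF <- LabelVolume(array(0, extF), spacing = 1)
    vM <- ImageVolume(array(rnorm(prod(extM)), extM), spacing = 1)
    lM <- LabelVolume(array(0, extM), spacing = 1)
    dvf <- predictDvf(net, vF, vM, lF, lM)
    expect_identical(extents(dvf), as.integer(extF))
    expect_identical(dim(dvfVectors(dvf))[4], 3L)
  }
})

test_that("inadmissible extents fail with the offending axis named", {
  cfg <- networkConfig(levels = 2, baseChannels = 2)
  net <- buildNetwork(cfg, seed = 8)
  mk <- function(ext) list(
    v = ImageVolume(array(0, ext), spacing = 1),
    l = LabelVolume(array(0, ext), spacing = 1))
  a <- mk(c(16, 14, 16))   # 14 not divisible by 4
  b <- mk(c(16, 16, 16))
  expect_error(predictDvf(net, a$v, b$v, a$l, b$l), "axis 2")
  expect_error(predictDvf(net, b$v, a$v, b$l, a$l), "axis 2")
  # moving larger than fixed is refused rather than silently cropped
  big <- mk(c(24, 16, 16))
  expect_error(predictDvf(net, b$v, big$v, b$l, big$l), "exceeds")
})

test_that("forward passes are deterministic", {
  cfg <- networkConfig(levels = 2, baseChannels = 4)
  net <- buildNetwork(cfg, seed = 9)
  for (nm in names(net@params))
    net@params[[nm]]$W <- net@params[[nm]]$W +
      array(rnorm(length(net@params[[nm]]$W), sd = 0.01),
            dim(net@params[[nm]]$W))
  ext <- c(16L, 16L, 16L)
  v <- ImageVolume(array(rnorm(prod(ext)), ext), spacing = 1)
  l <- LabelVolume((array(runif(prod(ext)), ext) > 0.8) * 1, spacing = 1)
  d1 <- predictDvf(net, v, v, l, l)
  d2 <- predictDvf(net, v, v, l, l)
  expect_identical(dvfVectors(d1), dvfVectors(d2))
})

test_that("convolution kernels match a naive oracle and their adjoints", {
  set.seed(40)
  X <- array(rnorm(2 * 5 * 4 * 6), c(2L, 5L, 4L, 6L))
  W <- array(rnorm(3 * 2 * 27), c(3L, 2L, 3L, 3L, 3L))
  b <- rnorm(3)
  Y <- array(siamreg:::c_conv3_fw(X, dim(X), W, dim(W), b), c(3L, 5L, 4L, 6L))
  expect_equal(Y, naiveConv3(X, W, b), tolerance = 1e-5)

  dY <- array(rnorm(length(Y)), dim(Y))
  gr <- siamreg:::c_conv3_bw(X, dim(X), W, dim(W), dY, TRUE)
  L <- function(Xa, Wa, ba) sum(naiveConv3(Xa, Wa, ba) * dY)
  eps <- 1e-4
  for (i in sample(length(X), 3)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    fd <- (L(Xp, W, b) - L(Xm, W, b)) / (2 * eps)
    expect_equal(gr$dX[i], fd, tolerance = 5e-3)
  }
  for (j in sample(length(W), 3)) {
    Wp <- W; Wp[j] <- Wp[j] + eps
    Wm <- W; Wm[j] <- Wm[j] - eps
    fd <- (L(X, Wp, b) - L(X, Wm, b)) / (2 * eps)
    expect_equal(gr$dW[j], fd, tolerance = 5e-3)
  }
  expect_equal(gr$db[2], sum(dY[2, , , ]), tolerance = 1e-4)
})

test_that("end-to-end network gradients match finite differences", {
  # all-active ReLU regime isolates the chain rule from kink noise
  cfg <- networkConfig(levels = 2, baseChannels = 2, useLabelChannels = FALSE)
  net <- buildNetwork(cfg, seed = 10)
  p <- net@params
  set.seed(41)
  for (nm in names(p)) { p[[nm]]$W <- p[[nm]]$W * 0.2; p[[nm]]$b[] <- 5 }
  p$final$W[] <- rnorm(length(p$final$W), sd = 0.02)
  xF <- array(runif(1 * 16 * 8 * 8), c(1L, 16L, 8L, 8L))
  xM <- array(runif(1 * 8 * 8 * 8), c(1L, 8L, 8L, 8L))
  fw <- siamreg:::.netForward(p, cfg, xF, xM, train = TRUE)
  dOut <- array(rnorm(length(fw$out), sd = 0.01), dim(fw$out))
  gr <- siamreg:::.netBackward(p, cfg, fw, dOut)
  L <- function(pp) sum(siamreg:::.netForward(pp, cfg, xF, xM)$out * dOut)
  eps <- 1e-2
  for (nm in c("first", "enc1.c2", "bott.c1", "dec2.c1", "dec1.c2", "final")) {
    # check the three largest gradients of the layer (above float32 noise)
    top <- order(abs(gr[[nm]]$dW), decreasing = TRUE)[1:3]
    for (i in top) {
      an <- gr[[nm]]$dW[i]
      pp <- p; pp[[nm]]$W[i] <- pp[[nm]]$W[i] + eps; up <- L(pp)
      pp[[nm]]$W[i] <- pp[[nm]]$W[i] - 2 * eps; dn <- L(pp)
      fd <- (up - dn) / (2 * eps)
      expect_equal(an, fd, tolerance = 0.05)
    }
  }
})

test_that("checkpoints round-trip the network", {
  cfg <- networkConfig(levels = 1, baseChannels = 2)
  net <- buildNetwork(cfg, seed = 11)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f, meta = list(iter = 7L))
  ck <- loadCheckpoint(f)
  expect_identical(ck$net@params, net@params)
  expect_identical(ck$meta$iter, 7L)
  saveRDS(list(format = "other"), f)
  expect_error(loadCheckpoint(f), "not a siamreg checkpoint")
})
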