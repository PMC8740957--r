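test_that("phantom generation is deterministic and anatomically sane", {
  cfg <- phantomConfig(extents = c(32, 32, 32), seed = 7)
  a <- makePhantom(cfg)
  b <- makePhantom(cfg)
  expect_identical(voxelData(a@fixed), voxelData(b@fixed))       # same seed
  expect_identical(voxelData(a@moving), voxelData(b@moving))
  expect_identical(landmarkTable(a@fixedLandmarks),
                   landmarkTable(b@fixedLandmarks))

  frac <- mean(voxelData(a@fixedLabel))
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
  expect_true(isBinary(a@fixedLabel))

  # the bifurcation landmark lies inside the lumen
  bif <- landmarkTable(a@fixedLandmarks)
  bif <- bif[bif$kind == "bifurcation", ]
  vox <- round(c(bif$x, bif$y, bif$z) / spacing(a@fixedLabel)) + 1
  expect_identical(voxelData(a@fixedLabel)[vox[1], vox[2], vox[3]], 1)
  # plus at least two wall/plaque stand-ins
  expect_gte(sum(landmarkTable(a@fixedLandmarks)$kind == "plaque"), 2L)

  # the two modality renderings share geometry but differ in contrast
  inLum <- voxelData(a@fixedLabel) == 1
  expect_gt(mean(voxelData(a@fixed)[inLum]), mean(voxelData(a@fixed)[!inLum]))
  expect_lt(mean(voxelData(a@moving)[inLum]), mean(voxelData(a@moving)[!inLum]))

  expect_error(phantomConfig(extents = c(10, 10, 32), radiusRange = c(4, 6)),
               "radius too large")
})

test_that("elastic fields respect the amplitude contract", {
  ext <- c(24L, 24L, 24L)
  z <- randomElasticDvf(ext, deformConfig(amplitude = 0, seed = 1))
  expect_identical(max(abs(dvfVectors(z))), 0)

  d <- randomElasticDvf(ext, deformConfig(amplitude = 2.5, seed = 2))
  mx <- max(sqrt(rowSums(matrix(dvfVectors(d), ncol = 3)^2)))
  expect_lt(abs(mx - 2.5), 1e-6)

  d2 <- randomElasticDvf(ext, deformConfig(amplitude = 2.5, seed = 2))
  expect_identical(dvfVectors(d), dvfVectors(d2))   # seeded determinism

  # more smoothing gives smoother fields, monotonically over sigma {1,2,4}
  sl <- vapply(c(1L, 2L, 4L), function(s)
    smoothnessLoss(randomElasticDvf(ext, deformConfig(amplitude = 3,
                                                      sigma = s, seed = 5))),
    1)
  expect_true(all(diff(sl) < 0))
})

test_that("deformed pairs store the aligning ground-truth field", {
  pr0 <- smallPair(seed = 3, amplitude = 0)
  # amplitude 0: moving equals the rendering, labels overlap perfectly
  expect_equal(dsc(pr0@fixedLabel, pr0@movingLabel), 1)

  pr <- smallPair(seed = 3, amplitude = 2)
  expect_lt(dsc(pr@fixedLabel, pr@movingLabel), 1)  # deformation breaks overlap

  # warping the moving label with the stored field recovers the fixed label
  rec <- warpVolume(pr@movingLabel, pr@gtDvf, interp = "trilinear")
  expect_gte(dsc(pr@fixedLabel, rec), 0.95)

  # TRE of the identity transform equals the mean |u| of the truth in mm
  idv <- identityDvf(extents(pr@fixed), spacing = spacing(pr@fixed))
  u <- dvfVectors(pr@gtDvf)
  meanU <- mean(sqrt(rowSums(sweep(matrix(u, ncol = 3), 2,
                                   spacing(pr@fixed), "*")^2)))
  expect_equal(tre(idv, pr@gtDvf, mask = NULL), meanU, tolerance = 1e-12)

  # like-named landmarks correspond: transporting fixed landmarks through
  # the truth lands on the moving landmarks
  expect_lt(landmarkDistance(pr@fixedLandmarks, pr@movingLandmarks,
                             pr@gtDvf), 0.15)
})

test_that("centered crops produce valid cross-scale pairs", {
  pr <- smallPair(seed = 4, amplitude = 2, extents = c(24L, 24L, 24L),
                  cropTo = c(16L, 16L, 24L))
  expect_identical(extents(pr@moving), c(16L, 16L, 24L))
  expect_identical(extents(pr@fixed), c(24L, 24L, 24L))
  expect_identical(extents(pr@movingLabel), c(16L, 16L, 24L))
  # origin shift keeps the cropped grid in the shared world frame
  expect_equal(origin(pr@moving), c(4, 4, 0) * 0.6)
  # the stored field still aligns the (cropped) moving label
  rec <- warpVolume(pr@movingLabel, pr@gtDvf, interp = "trilinear")
  expect_gt(dsc(pr@fixedLabel, rec), 0.8)
  expect_error(smallPair(seed = 4, cropTo = c(40, 16, 24)),
               "between 1 and the phantom extents")
})

test_that("left/right flip is a consistent involution", {
  pr <- smallPair(seed = 5, amplitude = 2)
  fl <- augmentPair(pr, "lr_flip")
  expect_false(identical(voxelData(fl@fixed), voxelData(pr@fixed)))
  back <- augmentPair(fl, "lr_flip")
  expect_identical(voxelData(back@fixed), voxelData(pr@fixed))
  expect_identical(voxelData(back@movingLabel), voxelData(pr@movingLabel))
  expect_identical(dvfVectors(back@gtDvf), dvfVectors(pr@gtDvf))
  expect_equal(landmarkTable(back@fixedLandmarks),
               landmarkTable(pr@fixedLandmarks))

  # mirroring both members together preserves the lumen overlap
  expect_equal(dsc(fl@fixedLabel, fl@movingLabel),
               dsc(pr@fixedLabel, pr@movingLabel), tolerance = 1e-12)
  # and the flipped field still aligns the flipped labels
  rec <- warpVolume(fl@movingLabel, fl@gtDvf, interp = "trilinear")
  expect_gte(dsc(fl@fixedLabel, rec), 0.95)
})

test_that("identity affine parameters leave a pair unchanged", {
  pr <- smallPair(seed = 6, amplitude = 2)
  idp <- list(angles = c(0, 0, 0), scale = 1, translate = c(0, 0, 0))
  same <- augmentPair(pr, "affine", params = idp)
  expect_equal(voxelData(same@fixed), voxelData(pr@fixed), tolerance = 1e-12)
  expect_identical(voxelData(same@movingLabel), voxelData(pr@movingLabel))
  expect_equal(dvfVectors(same@gtDvf), dvfVectors(pr@gtDvf),
               tolerance = 1e-12)
  expect_equal(landmarkTable(same@fixedLandmarks),
               landmarkTable(pr@fixedLandmarks), tolerance = 1e-10)
})

test_that("random affines transport labels and truth consistently", {
  pr <- smallPair(seed = 7, amplitude = 2)
  av <- augmentPair(pr, "affine", seed = 9)
  expect_false(identical(voxelData(av@fixed), voxelData(pr@fixed)))
  # the transported field still aligns the transformed labels well
  rec <- warpVolume(av@movingLabel, av@gtDvf, interp = "trilinear")
  expect_gt(dsc(av@fixedLabel, rec), 0.85)
  # same seed, same draw
  av2 <- augmentPair(pr, "affine", seed = 9)
  expect_identical(voxelData(av@fixed), voxelData(av2@fixed))
})

test_that("simulated datasets round-trip losslessly through the manifest", {
  dir <- file.path(tempdir(), "simds")
  mf <- simulateDataset(dir, nPairs = 2L, extents = c(16L, 16L, 16L),
                        deform = deformConfig(controlSpacing = 8L,
                                              amplitude = 1.5, sigma = 1L),
                        seed = 3L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(nrow(mf), 2L)
  pairs <- attr(mf, "pairs")
  loaded <- readManifest(file.path(dir, "manifest.csv"), load = TRUE)
  expect_length(loaded, 2L)
  for (i in 1:2) {
    expect_identical(voxelData(loaded[[i]]@fixed), voxelData(pairs[[i]]@fixed))
    expect_identical(voxelData(loaded[[i]]@movingLabel),
                     voxelData(pairs[[i]]@movingLabel))
    expect_identical(dvfVectors(loaded[[i]]@gtDvf),
                     dvfVectors(pairs[[i]]@gtDvf))
    expect_identical(loaded[[i]]@groupId, pairs[[i]]@groupId)
    expect_equal(landmarkTable(loaded[[i]]@fixedLandmarks),
                 landmarkTable(pairs[[i]]@fixedLandmarks), tolerance = 1e-9)
  }
})
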