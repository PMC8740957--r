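## Synthetic bifurcating-vessel phantoms.
##
## The generator stands in for clinical multi-sequence vessel MRI: a curved
## tube that splits into two branches (a Y-shaped lumen), rendered in two
## contrast profiles with inverted foreground/background means and
## independent noise -- the multi-modal condition that makes intensity
## similarity unusable and motivates label-driven (weakly supervised)
## registration. Binary lumen labels, a bifurcation landmark plus wall
## ("plaque") landmarks, ground-truth elastic deformation fields and the
## left/right-flip and affine augmentations complete the benchmark.

#' Phantom generation parameters
#'
#' @param extents grid extents (voxels)
#' @param spacing isotropic voxel size in mm
#' @param radiusRange (min, max) lumen radius in voxels; the trunk tapers
#'   from max to min along the vessel, branches are thinner
#' @param bifurcationFraction position of the branch point as a fraction of
#'   the vessel axis
#' @param fixedContrast,movingContrast lists with \code{fg}, \code{bg},
#'   \code{noiseSd}: mean intensities of lumen/background and additive
#'   Gaussian noise, for the two modality renderings
#' @param seed RNG seed; generation is fully deterministic given the seed
#' @export
phantomConfig <- function(extents = c(64L, 64L, 64L), spacing = 0.6,
                          radiusRange = c(3, 5), bifurcationFraction = 0.55,
                          fixedContrast = list(fg = 0.75, bg = 0.2,
                                               noiseSd = 0.03),
                          movingContrast = list(fg = 0.3, bg = 0.7,
                                                noiseSd = 0.03),
                          seed = 1L) {
  extents <- as.integer(extents)
  stopifnot(length(extents) == 3L, all(extents >= 8L),
            radiusRange[1] >= 1, radiusRange[2] >= radiusRange[1],
            bifurcationFraction > 0, bifurcationFraction < 1)
  if (2 * radiusRange[2] + 4 > min(extents[1:2]))
    stop("vessel radius too large for the grid extents")
  list(extents = extents, spacing = spacing, radiusRange = radiusRange,
       bifurcationFraction = bifurcationFraction,
       fixedContrast = fixedContrast, movingContrast = movingContrast,
       seed = as.integer(seed))
}

#' Elastic deformation parameters
#'
#' Random vectors on a coarse control grid, trilinearly up-sampled,
#' Gaussian-smoothed, and scaled so the maximum displacement magnitude
#' equals \code{amplitude}.
#'
#' @param controlSpacing control-point spacing in voxels
#' @param amplitude maximum displacement magnitude in voxels (0 gives the
#'   identity field)
#' @param sigma non-negative integer smoothing standard deviation (voxels)
#' @param seed RNG seed
#' @export
deformConfig <- function(controlSpacing = 12L, amplitude = 3, sigma = 2L,
                         seed = 1L) {
  stopifnot(controlSpacing >= 2, amplitude >= 0, sigma >= 0)
  list(controlSpacing = as.integer(controlSpacing),
       amplitude = amplitude, sigma = as.integer(sigma),
       seed = as.integer(seed))
}

# centreline positions and radii for every z slice; trunk then two branches
.vesselGeometry <- function(ext, rr, bifFrac) {
  n3 <- ext[3]
  zb <- max(2L, min(n3 - 2L, as.integer(round(bifFrac * n3))))
  z <- seq_len(n3) - 1
  wob <- function(amp) amp * sin(pi * z / n3 * stats::runif(1, 0.8, 1.6) +
                                 stats::runif(1, 0, 2 * pi))
  cx <- (ext[1] - 1) / 2 + wob(stats::runif(1, 1, 3))
  cy <- (ext[2] - 1) / 2 + wob(stats::runif(1, 1, 3))
  r <- rr[2] - (rr[2] - rr[1]) * z / n3
  slope <- stats::runif(1, 0.3, 0.5)
  margin <- rr[2] + 2
  post <- z > zb
  dx <- slope * (z - zb) * post
  b1x <- pmin(pmax(cx + dx, margin), ext[1] - 1 - margin)
  b2x <- pmin(pmax(cx - dx, margin), ext[1] - 1 - margin)
  list(zb = zb, cx = cx, cy = cy, r = r, b1x = b1x, b2x = b2x, post = post)
}

.rasterizeLumen <- function(ext, geo) {
  lab <- array(0, ext)
  xs <- seq_len(ext[1]) - 1
  ys <- seq_len(ext[2]) - 1
  for (zi in seq_len(ext[3])) {
    r2 <- geo$r[zi]^2
    inside <- if (!geo$post[zi]) {
      outer((xs - geo$cx[zi])^2, (ys - geo$cy[zi])^2, "+") <= r2
    } else {
      rb2 <- (0.8 * geo$r[zi])^2
      (outer((xs - geo$b1x[zi])^2, (ys - geo$cy[zi])^2, "+") <= rb2) |
      (outer((xs - geo$b2x[zi])^2, (ys - geo$cy[zi])^2, "+") <= rb2)
    }
    lab[, , zi] <- inside
  }
  lab
}

.renderModality <- function(lab, contrast) {
  s <- .smoothArray(lab, gaussianKernel(1))      # partial-volume soft edge
  contrast$bg + (contrast$fg - contrast$bg) * s +
    stats::rnorm(length(lab), sd = contrast$noiseSd)
}

#' Generate an undeformed vessel phantom pair
#'
#' Both modality renderings share identical geometry (and therefore one
#' lumen label and landmark set); only the intensity mapping and the noise
#' realization differ. Landmarks: the bifurcation point and wall points
#' standing in for plaque positions.
#'
#' @param cfg a \code{\link{phantomConfig}}
#' @param groupId patient/group identifier attached to the pair
#' @return a \linkS4class{RegistrationPair} (no deformation, no gtDvf)
#' @export
makePhantom <- function(cfg = phantomConfig(), groupId = "g1") {
  ext <- cfg$extents
  sp <- rep(cfg$spacing, 3)
  .withSeed(cfg$seed, {
    geo <- .vesselGeometry(ext, cfg$radiusRange, cfg$bifurcationFraction)
    lab <- .rasterizeLumen(ext, geo)
    fixedImg <- array(.renderModality(lab, cfg$fixedContrast), ext)
    movingImg <- array(.renderModality(lab, cfg$movingContrast), ext)
    zb <- geo$zb
    zi1 <- max(1L, as.integer(round(0.25 * ext[3])))
    zi2 <- min(ext[3], as.integer(round(0.85 * ext[3])))
    vox <- rbind(
      bifurcation = c(geo$cx[zb + 1], geo$cy[zb + 1], zb),
      plaque_wall_low = c(geo$cx[zi1] + 0.6 * geo$r[zi1], geo$cy[zi1],
                          zi1 - 1),
      plaque_wall_high = c(geo$b1x[zi2], geo$cy[zi2] + 0.5 * geo$r[zi2],
                           zi2 - 1))
    lms <- LandmarkSet(name = rownames(vox),
                       coords = sweep(vox, 2, sp, "*"),
                       kind = c("bifurcation", "plaque", "plaque"))
    labv <- LabelVolume(lab, spacing = sp)
    RegistrationPair(
      fixed = ImageVolume(fixedImg, spacing = sp),
      moving = ImageVolume(movingImg, spacing = sp),
      fixedLabel = labv, movingLabel = labv,
      fixedLandmarks = lms, movingLandmarks = lms,
      groupId = groupId)
  })
}

#' Random elastic displacement field
#'
#' Independent Gaussian vectors on a coarse control grid are trilinearly
#' up-sampled to the full grid, smoothed with an isotropic Gaussian, and
#' rescaled so the maximum displacement magnitude equals the configured
#' amplitude.
#'
#' @param extents fixed-grid extents
#' @param cfg a \code{\link{deformConfig}}
#' @param spacing,origin geometry attached to the returned field
#' @return a \linkS4class{DisplacementField}
#' @export
randomElasticDvf <- function(extents, cfg = deformConfig(),
                             spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  extents <- as.integer(extents)
  if (cfg$amplitude == 0)
    return(identityDvf(extents, spacing = spacing, origin = origin))
  .withSeed(cfg$seed, {
    nc <- pmax(2L, as.integer(ceiling((extents - 1) / cfg$controlSpacing)) + 1L)
    pts <- .gridCoords(extents, rep(1 / cfg$controlSpacing, 3))
    u <- array(0, c(extents, 3L))
    kern <- gaussianKernel(cfg$sigma)
    for (c in 1:3) {
      ctrl <- array(stats::rnorm(prod(nc)), nc)
      comp <- array(c_sample_points(ctrl, nc, pts, 1L, 1L), extents)
      u[, , , c] <- .smoothArray(comp, kern)
    }
    mx <- max(sqrt(rowSums(matrix(u, ncol = 3)^2)))
    if (mx > 0) u <- u * (cfg$amplitude / mx)
    DisplacementField(u, spacing = spacing, origin = origin)
  })
}

# fixed-grid positions x solving x + u(x) = p for moving positions p
.invertAtPoints <- function(dvf, voxPts, iters = 30L) {
  x <- voxPts
  for (i in seq_len(iters)) {
    u <- .sampleDvf(dvf, x)
    if (is.null(dim(u))) u <- matrix(u, nrow = nrow(x))
    x <- voxPts - u
  }
  x
}

#' Build a deformed registration pair with ground truth
#'
#' The moving side keeps the pristine moving-modality rendering; the fixed
#' side is produced by backward-sampling the fixed-modality rendering (and
#' the lumen label) through a random elastic field u. The stored gtDvf is
#' therefore exactly the field that aligns the moving image onto the fixed
#' grid: warp(moving, gtDvf) reproduces the fixed geometry by construction.
#' Fixed landmarks are obtained by fixed-point inversion of u at the moving
#' landmark positions, so like-named landmarks correspond anatomically.
#'
#' An optional centered crop of the moving side emulates the cross-scale
#' regime where the moving grid is smaller than the fixed grid.
#'
#' @param phantom an undeformed pair from \code{\link{makePhantom}}
#' @param cfg a \code{\link{deformConfig}}
#' @param cropTo optional moving-side extents after centered cropping
#' @param divisibleBy optionally require the final extents to be divisible
#'   by this (the network's 2^levels constraint), erroring early otherwise
#' @return a \linkS4class{RegistrationPair} with gtDvf set
#' @export
makeDeformedPair <- function(phantom, cfg = deformConfig(), cropTo = NULL,
                             divisibleBy = NULL) {
  stopifnot(is(phantom, "RegistrationPair"))
  ext <- dim(phantom@fixed@data)
  sp <- phantom@fixed@spacing
  u <- randomElasticDvf(ext, cfg, spacing = sp, origin = phantom@fixed@origin)
  fixedVol <- warpVolume(phantom@fixed, u, interp = "trilinear",
                         oob = "border")
  fixedLab <- warpVolume(phantom@fixedLabel, u, interp = "trilinear",
                         oob = "zero")
  fixedLab@data <- (fixedLab@data >= 0.5) * 1
  mlm <- phantom@movingLandmarks
  voxP <- sweep(sweep(as.matrix(mlm@points[, c("x", "y", "z")]), 2,
                      phantom@moving@origin, "-"), 2, sp, "/")
  fvox <- .invertAtPoints(u, voxP)
  flm <- LandmarkSet(name = mlm@points$name,
                     coords = sweep(fvox, 2, sp, "*") +
                       matrix(phantom@fixed@origin, nrow(fvox), 3,
                              byrow = TRUE),
                     kind = mlm@points$kind)
  movingVol <- phantom@moving
  movingLab <- phantom@movingLabel
  if (!is.null(cropTo)) {
    cropTo <- as.integer(cropTo)
    if (any(cropTo > ext) || any(cropTo < 1L))
      stop("cropTo must be between 1 and the phantom extents")
    lo <- (ext - cropTo) %/% 2L
    movingVol <- cropVolume(movingVol, lo, lo + cropTo)
    movingLab <- cropVolume(movingLab, lo, lo + cropTo)
    mlm <- suppressWarnings(cropLandmarkSet(mlm, phantom@moving, lo,
                                            lo + cropTo))
  }
  if (!is.null(divisibleBy)) {
    bad <- c(dim(fixedVol@data), dim(movingVol@data)) %% divisibleBy != 0
    if (any(bad))
      stop("extents are not divisible by ", divisibleBy,
           "; incompatible with the network's pooling depth")
  }
  RegistrationPair(fixed = fixedVol, moving = movingVol,
                   fixedLabel = fixedLab, movingLabel = movingLab,
                   fixedLandmarks = flm, movingLandmarks = mlm,
                   gtDvf = u, groupId = phantom@groupId)
}

.flipVol <- function(v) {
  n <- dim(v@data)[1]
  initialize(v, data = v@data[n:1, , , drop = FALSE])
}

.affineOf <- function(params) {
  ang <- params$angles
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  (Rz %*% Ry %*% Rx) * params$scale
}

.affineResample <- function(v, A, tr, isLabel) {
  ext <- dim(v@data)
  cen <- (ext - 1) / 2
  pts <- .gridCoords(ext, c(1, 1, 1))
  pts <- sweep(pts, 2, cen, "-") %*% t(A)
  pts <- sweep(pts, 2, cen + tr, "+")
  vals <- c_sample_points(v@data, ext, pts, 1L, if (isLabel) 0L else 1L)
  a <- array(vals, ext)
  if (isLabel) a <- (a >= 0.5) * 1
  initialize(v, data = a)
}

#' Augment a registration pair
#'
#' \code{lr_flip} mirrors volumes, labels, landmarks and the ground-truth
#' field along the left-right axis (negating the corresponding field
#' component); applying it twice is the identity. \code{affine} applies one
#' small random rotation/scale/translation identically to both members
#' (about each grid's centre), transporting the ground-truth field through
#' the same transform. Flipping is the offline dataset-doubling
#' augmentation; affine is the on-the-fly training augmentation.
#'
#' @param pair RegistrationPair
#' @param mode "lr_flip" or "affine"
#' @param seed RNG seed for random affine parameters (ignored by lr_flip)
#' @param params optional explicit affine parameters:
#'   \code{list(angles = c(rx, ry, rz) [rad], scale, translate [voxels])}
#' @export
augmentPair <- function(pair, mode = c("lr_flip", "affine"), seed = 1L,
                        params = NULL) {
  mode <- match.arg(mode)
  if (mode == "lr_flip") {
    flipLms <- function(lms, vol) {
      if (is.null(lms)) return(NULL)
      p <- lms@points
      cx <- vol@origin[1] + (dim(vol@data)[1] - 1) * vol@spacing[1] / 2
      p$x <- 2 * cx - p$x
      new("LandmarkSet", points = p)
    }
    gt <- pair@gtDvf
    if (!is.null(gt)) {
      n <- dim(gt@vectors)[1]
      v <- gt@vectors[n:1, , , , drop = FALSE]
      v[, , , 1] <- -v[, , , 1]
      gt <- initialize(gt, vectors = v)
    }
    return(RegistrationPair(
      fixed = .flipVol(pair@fixed), moving = .flipVol(pair@moving),
      fixedLabel = if (!is.null(pair@fixedLabel)) .flipVol(pair@fixedLabel),
      movingLabel = if (!is.null(pair@movingLabel)) .flipVol(pair@movingLabel),
      fixedLandmarks = flipLms(pair@fixedLandmarks, pair@fixed),
      movingLandmarks = flipLms(pair@movingLandmarks, pair@moving),
      gtDvf = gt, groupId = pair@groupId))
  }
  if (is.null(params))
    params <- .withSeed(seed, list(
      angles = stats::runif(3, -5, 5) * pi / 180,
      scale = stats::runif(1, 0.95, 1.05),
      translate = stats::runif(3, -2, 2)))
  A <- .affineOf(params)
  Ainv <- solve(A)
  tr <- params$translate
  affLms <- function(lms, vol) {
    if (is.null(lms) || !nrow(lms@points)) return(lms)
    p <- lms@points
    ext <- dim(vol@data)
    cen <- (ext - 1) / 2
    vox <- sweep(sweep(as.matrix(p[, c("x", "y", "z")]), 2, vol@origin, "-"),
                 2, vol@spacing, "/")
    vox <- sweep(sweep(vox, 2, cen + tr, "-") %*% t(Ainv), 2, cen, "+")
    wc <- sweep(sweep(vox, 2, vol@spacing, "*"), 2, vol@origin, "+")
    LandmarkSet(name = p$name, coords = wc, kind = p$kind)
  }
  gt <- pair@gtDvf
  if (!is.null(gt)) {
    ext <- dim(gt@vectors)[1:3]
    cen <- (ext - 1) / 2
    pts <- .gridCoords(ext, c(1, 1, 1))
    pts <- sweep(sweep(pts, 2, cen, "-") %*% t(A), 2, cen + tr, "+")
    U <- vapply(1:3, function(c)
      c_sample_points(gt@vectors[, , , c], ext, pts, 1L, 1L),
      numeric(nrow(pts)))
    gt <- initialize(gt, vectors = array(U %*% t(Ainv), c(ext, 3L)))
  }
  RegistrationPair(
    fixed = .affineResample(pair@fixed, A, tr, FALSE),
    moving = .affineResample(pair@moving, A, tr, FALSE),
    fixedLabel = if (!is.null(pair@fixedLabel))
      .affineResample(pair@fixedLabel, A, tr, TRUE),
    movingLabel = if (!is.null(pair@movingLabel))
      .affineResample(pair@movingLabel, A, tr, TRUE),
    fixedLandmarks = affLms(pair@fixedLandmarks, pair@fixed),
    movingLandmarks = affLms(pair@movingLandmarks, pair@moving),
    gtDvf = gt, groupId = pair@groupId)
}

#' Simulate a phantom dataset on disk
#'
#' Generates deformed phantom pairs, writes NIfTI volumes/labels/fields and
#' landmark tables into a directory, and a \code{manifest.csv} listing the
#' pairs with their group ids (two consecutive pairs share a group,
#' emulating left/right vessels of one patient).
#'
#' @param dir output directory (created if needed)
#' @param nPairs number of pairs
#' @param extents phantom grid extents
#' @param spacing voxel size in mm
#' @param radiusRange lumen radius range passed to
#'   \code{\link{phantomConfig}}
#' @param deform a \code{\link{deformConfig}} template (per-pair seeds are
#'   derived from \code{seed})
#' @param cropTo optional moving-side extents (cross-scale datasets)
#' @param pairsPerGroup pairs sharing one group id (default 2)
#' @param seed master seed
#' @return the manifest data.frame (invisibly, with attribute \code{pairs}:
#'   the in-memory list of RegistrationPair objects)
#' @export
simulateDataset <- function(dir, nPairs = 12L, extents = c(48L, 48L, 48L),
                            spacing = 0.6, radiusRange = c(3, 5),
                            deform = deformConfig(), cropTo = NULL,
                            pairsPerGroup = 2L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .withSeed(seed, matrix(sample.int(1e8, 2L * nPairs), ncol = 2))
  rows <- vector("list", nPairs)
  pairs <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    gid <- sprintf("g%02d", (i - 1L) %/% pairsPerGroup + 1L)
    ph <- makePhantom(phantomConfig(extents = extents, spacing = spacing,
                                    radiusRange = radiusRange,
                                    seed = seeds[i, 1]), groupId = gid)
    dcfg <- deform
    dcfg$seed <- seeds[i, 2]
    pr <- makeDeformedPair(ph, dcfg, cropTo = cropTo)
    pid <- sprintf("pair%03d", i)
    f <- function(suffix) paste0(pid, "_", suffix)
    writeVolume(pr@fixed, file.path(dir, f("fixed.nii.gz")))
    writeVolume(pr@fixedLabel, file.path(dir, f("fixed_label.nii.gz")))
    writeVolume(pr@moving, file.path(dir, f("moving.nii.gz")))
    writeVolume(pr@movingLabel, file.path(dir, f("moving_label.nii.gz")))
    writeLandmarkSet(pr@fixedLandmarks, file.path(dir, f("fixed_landmarks.txt")))
    writeLandmarkSet(pr@movingLandmarks, file.path(dir, f("moving_landmarks.txt")))
    writeDvf(pr@gtDvf, file.path(dir, f("gt_dvf.nii.gz")))
    rows[[i]] <- data.frame(
      pair_id = pid, group_id = gid,
      fixed = f("fixed.nii.gz"), fixed_label = f("fixed_label.nii.gz"),
      fixed_landmarks = f("fixed_landmarks.txt"),
      moving = f("moving.nii.gz"), moving_label = f("moving_label.nii.gz"),
      moving_landmarks = f("moving_landmarks.txt"),
      gt_dvf = f("gt_dvf.nii.gz"), stringsAsFactors = FALSE)
    pairs[[i]] <- pr
  }
  mf <- do.call(rbind, rows)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(mf, "pairs") <- pairs
  invisible(mf)
}
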