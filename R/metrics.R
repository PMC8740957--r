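## Evaluation metrics: Dice similarity coefficient on hard masks, mean
## landmark distance (Lm.Dist) and target registration error (TRE).

#' Dice similarity coefficient
#'
#' Binarizes both maps at \code{threshold} and returns
#' \code{2 |A ∩ B| / (|A| + |B|)}. Two empty masks agree vacuously:
#' the value is 1. Evaluation uses hard masks, distinct from the soft
#' training losses.
#'
#' @param a,b label maps (LabelVolume or 3D array) with equal extents
#' @param threshold binarization threshold (default 0.5)
#' @export
dsc <- function(a, b, threshold = 0.5) {
  aa <- .asLabelArray(a) >= threshold
  bb <- .asLabelArray(b) >= threshold
  if (!identical(dim(aa), dim(bb)))
    stop(sprintf("mask extents differ: %s vs %s",
                 paste(dim(aa), collapse = "x"),
                 paste(dim(bb), collapse = "x")))
  sa <- sum(aa); sb <- sum(bb)
  if (sa + sb == 0) return(1)
  2 * sum(aa & bb) / (sa + sb)
}

#' Mean landmark distance (Lm.Dist)
#'
#' Transports every fixed-space landmark through the displacement field
#' (fixed-to-moving direction) and returns the mean Euclidean distance in mm
#' to the like-named moving landmark. Points flagged outside the grid are
#' excluded with a warning.
#'
#' @param fixedPts,movingPts LandmarkSet with shared names
#' @param dvf DisplacementField on the fixed grid
#' @export
landmarkDistance <- function(fixedPts, movingPts, dvf) {
  stopifnot(is(fixedPts, "LandmarkSet"), is(movingPts, "LandmarkSet"))
  common <- intersect(fixedPts@points$name, movingPts@points$name)
  if (!length(common))
    stop("the two landmark sets share no names")
  moved <- transportLandmarks(fixedPts, dvf)
  valid <- attr(moved@points, "valid")
  if (is.null(valid)) valid <- rep(TRUE, nrow(moved@points))
  mp <- moved@points[match(common, moved@points$name), ]
  vv <- valid[match(common, moved@points$name)]
  tp <- movingPts@points[match(common, movingPts@points$name), ]
  d <- sqrt((mp$x - tp$x)^2 + (mp$y - tp$y)^2 + (mp$z - tp$z)^2)
  if (any(!vv)) {
    warning(sum(!vv), " landmark(s) excluded from the mean (outside grid)")
    d <- d[vv]
  }
  mean(d)
}

#' Target registration error (TRE)
#'
#' Mean over voxels of the Euclidean norm of the difference between a
#' predicted and a ground-truth displacement field, converted to mm through
#' the voxel spacing. By default the mean runs over the foreground of
#' \code{mask} (errors in empty background carry no anatomical meaning);
#' pass \code{mask = NULL} for the whole grid.
#'
#' @param pred,truth DisplacementField with equal extents and spacing
#' @param mask optional LabelVolume restricting the average
#' @export
tre <- function(pred, truth, mask = NULL) {
  stopifnot(is(pred, "DisplacementField"), is(truth, "DisplacementField"))
  if (!identical(dim(pred@vectors), dim(truth@vectors)))
    stop("field extents differ")
  if (max(abs(pred@spacing - truth@spacing)) > 1e-6)
    stop("field spacings differ")
  dmm <- matrix(pred@vectors - truth@vectors, ncol = 3)
  dmm <- sweep(dmm, 2, pred@spacing, "*")
  nrm <- sqrt(rowSums(dmm^2))
  if (!is.null(mask)) {
    m <- as.vector(.asLabelArray(mask) >= 0.5)
    if (length(m) != length(nrm)) stop("mask extents differ from the fields")
    if (!any(m)) stop("mask is empty")
    nrm <- nrm[m]
  }
  mean(nrm)
}

#' Evaluate registration over a set of pairs
#'
#' For every pair: lumen DSC before registration (identity transform) and
#' after (hard-warped moving label), mean landmark distance before/after
#' where landmarks are present, TRE against the ground-truth field where one
#' is stored, and the wall time of the network forward pass.
#'
#' @param net SiameseUNet
#' @param pairs list of RegistrationPair
#' @return data.frame with one row per pair
#' @export
evaluatePairs <- function(net, pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    idDvf <- identityDvf(dim(pr@fixed@data), spacing = pr@fixed@spacing,
                         origin = pr@fixed@origin)
    t0 <- proc.time()[["elapsed"]]
    dvf <- predictDvf(net, pr@fixed, pr@moving, pr@fixedLabel, pr@movingLabel)
    rt <- proc.time()[["elapsed"]] - t0
    pre <- dsc(pr@fixedLabel, warpVolume(pr@movingLabel, idDvf,
                                         interp = "nearest"))
    post <- dsc(pr@fixedLabel, warpVolume(pr@movingLabel, dvf,
                                          interp = "nearest"))
    lmPre <- lmPost <- NA_real_
    if (!is.null(pr@fixedLandmarks) && !is.null(pr@movingLandmarks) &&
        nrow(pr@fixedLandmarks@points)) {
      lmPre <- landmarkDistance(pr@fixedLandmarks, pr@movingLandmarks, idDvf)
      lmPost <- landmarkDistance(pr@fixedLandmarks, pr@movingLandmarks, dvf)
    }
    treId <- trePost <- NA_real_
    if (!is.null(pr@gtDvf)) {
      treId <- tre(idDvf, pr@gtDvf, mask = pr@fixedLabel)
      trePost <- tre(dvf, pr@gtDvf, mask = pr@fixedLabel)
    }
    data.frame(pair = i, group = pr@groupId, dsc_pre = pre, dsc_post = post,
               lmdist_pre = lmPre, lmdist_post = lmPost, tre_identity = treId,
               tre_post = trePost, runtime_s = rt)
  })
  do.call(rbind, rows)
}
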