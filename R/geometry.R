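## Geometric preprocessing: isotropic resampling, cropping, left/right
## splitting. Conventions: 0-based voxel indices, half-open crop boxes
## [lo, hi); world mm = origin + index * spacing.

.gridCoords <- function(ext, scale) {
  # all voxel-centre coordinates of a grid with extents ext, multiplied
  # per-axis by scale; rows ordered like the array in memory
  cbind(rep.int(seq_len(ext[1]) - 1, ext[2] * ext[3]) * scale[1],
        rep.int(rep(seq_len(ext[2]) - 1, each = ext[1]), ext[3]) * scale[2],
        rep(seq_len(ext[3]) - 1, each = ext[1] * ext[2]) * scale[3])
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto a grid with extents
#' \code{round(extent * spacing / target)} per axis (at least 1). The origin
#' is unchanged; samples beyond the source extent clamp to the border so a
#' constant volume stays constant.
#'
#' @param v ImageVolume (or LabelVolume, which stays a LabelVolume; warped
#'   values are clamped to [0,1])
#' @param targetSpacing new isotropic voxel size in mm, > 0
#' @return resampled volume of the same class
#' @export
resampleIsotropic <- function(v, targetSpacing) {
  stopifnot(is(v, "ImageVolume"))
  if (!is.numeric(targetSpacing) || length(targetSpacing) != 1L ||
      !is.finite(targetSpacing) || targetSpacing <= 0)
    stop("targetSpacing must be a single positive number")
  ext <- dim(v@data)
  newExt <- pmax(1L, as.integer(round(ext * v@spacing / targetSpacing)))
  pts <- .gridCoords(newExt, rep(targetSpacing, 3) / v@spacing)
  vals <- c_sample_points(v@data, ext, pts, 1L, 1L)
  a <- array(vals, newExt)
  if (is(v, "LabelVolume")) a <- pmin(pmax(a, 0), 1)
  initialize(v, data = a, spacing = rep(targetSpacing, 3), origin = v@origin)
}

#' Crop a volume to a half-open voxel box
#'
#' Indices are 0-based and the box is half-open per axis: voxels
#' \code{lo .. hi-1} are kept. The origin shifts by \code{lo * spacing}.
#'
#' @param v ImageVolume or LabelVolume
#' @param lo,hi integer triples, 0 <= lo < hi <= extents
#' @export
cropVolume <- function(v, lo, hi) {
  stopifnot(is(v, "ImageVolume"))
  ext <- dim(v@data)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 0L) ||
      any(hi > ext) || any(lo >= hi))
    stop(sprintf("invalid crop box [%s, %s) for extents %s",
                 paste(lo, collapse = ","), paste(hi, collapse = ","),
                 paste(ext, collapse = "x")))
  a <- v@data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
              drop = FALSE]
  initialize(v, data = a, origin = v@origin + lo * v@spacing)
}

#' Drop landmarks outside a crop box
#'
#' Landmarks are stored in world mm, so cropping a volume only removes the
#' points whose positions fall outside the retained voxel-centre range;
#' dropped points are reported with a warning.
#'
#' @param lms LandmarkSet
#' @param v the (uncropped) reference volume
#' @param lo,hi the crop box passed to \code{\link{cropVolume}}
#' @export
cropLandmarkSet <- function(lms, v, lo, hi) {
  stopifnot(is(lms, "LandmarkSet"), is(v, "ImageVolume"))
  p <- lms@points
  if (!nrow(p)) return(lms)
  wlo <- v@origin + lo * v@spacing
  whi <- v@origin + (hi - 1) * v@spacing
  keep <- p$x >= wlo[1] & p$x <= whi[1] &
          p$y >= wlo[2] & p$y <= whi[2] &
          p$z >= wlo[3] & p$z <= whi[3]
  if (any(!keep))
    warning(sum(!keep), " landmark(s) outside the crop box dropped: ",
            paste(p$name[!keep], collapse = ", "))
  new("LandmarkSet", points = p[keep, , drop = FALSE])
}

#' Split a volume into left and right halves
#'
#' Splits along the left-right axis at \code{floor(extent/2)}; with an odd
#' extent the extra slice goes to the second half. Concatenating the halves
#' along the split axis reproduces the original grid.
#'
#' @param v ImageVolume or LabelVolume
#' @param axis the left-right axis (default 1)
#' @return list with elements \code{left} and \code{right}
#' @export
splitLeftRight <- function(v, axis = 1L) {
  stopifnot(is(v, "ImageVolume"), axis %in% 1:3)
  n <- dim(v@data)[axis]
  if (n < 2L) stop("left-right extent must be at least 2 to split")
  half <- n %/% 2L
  lo1 <- c(0L, 0L, 0L); hi1 <- dim(v@data); hi1[axis] <- half
  lo2 <- c(0L, 0L, 0L); lo2[axis] <- half
  list(left = cropVolume(v, lo1, hi1), right = cropVolume(v, lo2, dim(v@data)))
}
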