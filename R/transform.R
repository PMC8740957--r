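## Applying displacement fields: backward-mapping resampling of the moving
## image/label on the fixed grid, and transport of landmark points.
##
## The field u lives on the fixed grid in voxel units: output voxel x is
## sampled from the moving image at x + u(x) (plus the origin offset between
## the two grids, so cropped moving volumes resolve to the right voxels).

#' Identity displacement field
#' @param extents fixed-grid extents (3 integers)
#' @param spacing mm per voxel
#' @param origin world origin
#' @export
identityDvf <- function(extents, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  extents <- as.integer(extents)
  stopifnot(length(extents) == 3L, all(extents >= 1L))
  DisplacementField(array(0, c(extents, 3L)), spacing = spacing,
                    origin = origin)
}

.interpCode <- function(interp) match(interp, c("nearest", "trilinear")) - 1L
.oobCode <- function(oob) match(oob, c("zero", "border")) - 1L

#' Warp a volume or label with a displacement field
#'
#' Backward mapping: every output voxel x on the fixed grid gathers the
#' moving-image value at x + u(x) (voxel coordinates). The moving grid may
#' have different extents (the cross-scale case); differing origins are
#' honoured through the shared world frame. Out-of-bounds behaviour defaults
#' to border clamping for images (no dark rims) and zero for labels (no
#' anatomy outside the field of view). Labels warped with trilinear
#' interpolation become soft maps in [0,1], the form the soft Dice losses
#' consume; use nearest for hard evaluation masks.
#'
#' @param moving ImageVolume or LabelVolume
#' @param dvf DisplacementField on the fixed grid
#' @param interp "trilinear" or "nearest"
#' @param oob "auto" (border for images, zero for labels), "zero" or "border"
#' @return warped volume of the same class on the fixed grid
#' @export
warpVolume <- function(moving, dvf, interp = c("trilinear", "nearest"),
                       oob = c("auto", "zero", "border")) {
  stopifnot(is(moving, "ImageVolume"), is(dvf, "DisplacementField"))
  interp <- match.arg(interp)
  oob <- match.arg(oob)
  if (oob == "auto") oob <- if (is(moving, "LabelVolume")) "zero" else "border"
  u <- dvf@vectors
  shift <- (dvf@origin - moving@origin) / moving@spacing
  if (any(abs(shift) > 1e-9)) {
    for (c in 1:3) u[, , , c] <- u[, , , c] + shift[c]
  }
  odim <- dim(u)[1:3]
  vals <- c_warp(moving@data, dim(moving@data), u, odim,
                 .interpCode(interp), .oobCode(oob))
  a <- array(vals, odim)
  if (is(moving, "LabelVolume")) a <- pmin(pmax(a, 0), 1)
  initialize(moving, data = a, spacing = dvf@spacing, origin = dvf@origin)
}

# trilinear interpolation of the field at fixed-grid voxel coordinates
.sampleDvf <- function(dvf, vox) {
  d <- dim(dvf@vectors)[1:3]
  vapply(1:3, function(c)
    c_sample_points(dvf@vectors[, , , c], d, vox, 1L, 1L),
    numeric(nrow(vox)))
}

#' Transport landmarks through a displacement field
#'
#' Each fixed-space point x (world mm) is mapped to x + u(x) * spacing,
#' with u interpolated trilinearly at the point's voxel position -- the
#' predicted moving-space position to compare against moving landmarks.
#' Points outside the fixed grid are flagged (\code{valid} attribute) and
#' excluded from downstream means with a warning.
#'
#' @param pts LandmarkSet in fixed-image world coordinates
#' @param dvf DisplacementField on the fixed grid
#' @return LandmarkSet of transported points, with a logical \code{valid}
#'   attribute marking points that were inside the grid
#' @export
transportLandmarks <- function(pts, dvf) {
  stopifnot(is(pts, "LandmarkSet"), is(dvf, "DisplacementField"))
  p <- pts@points
  if (!nrow(p)) return(pts)
  ext <- dim(dvf@vectors)[1:3]
  vox <- sweep(sweep(as.matrix(p[, c("x", "y", "z")]), 2, dvf@origin, "-"),
               2, dvf@spacing, "/")
  valid <- vox[, 1] >= 0 & vox[, 1] <= ext[1] - 1 &
           vox[, 2] >= 0 & vox[, 2] <= ext[2] - 1 &
           vox[, 3] >= 0 & vox[, 3] <= ext[3] - 1
  if (any(!valid))
    warning(sum(!valid), " landmark(s) outside the fixed grid flagged invalid")
  u <- .sampleDvf(dvf, vox)
  if (nrow(p) == 1L) u <- matrix(u, nrow = 1L)
  moved <- as.matrix(p[, c("x", "y", "z")]) +
    sweep(u, 2, dvf@spacing, "*")
  out <- LandmarkSet(name = p$name, coords = moved, kind = p$kind)
  attr(out@points, "valid") <- valid
  out
}
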