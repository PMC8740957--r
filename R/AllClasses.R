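#' @import methods
NULL

#' 3D image volume
#'
#' A scalar 3D grid with isotropic or anisotropic voxel spacing and a world
#' origin. World coordinates (mm) of voxel index \code{i} (0-based) are
#' \code{origin + i * spacing}.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel along each axis, strictly positive.
#' @slot origin numeric(3), world mm coordinates of voxel (0,0,0).
#' @exportClass ImageVolume
setClass("ImageVolume",
  slots = c(data = "array", spacing = "numeric", origin = "numeric"),
  prototype = list(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 1L)) return("all grid extents must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  if (anyNA(d) || any(!is.finite(d))) return("intensities must be finite")
  TRUE
})

#' Label map aligned to a volume
#'
#' A 3D grid of values in [0,1] on the same geometry as a companion
#' \linkS4class{ImageVolume}. Binary masks hold values in \{0,1\}; Gaussian
#' smoothing and trilinear warping produce soft values.
#'
#' @exportClass LabelVolume
setClass("LabelVolume", contains = "ImageVolume")

setValidity("LabelVolume", function(object) {
  r <- range(object@data)
  if (r[1] < 0 || r[2] > 1) return("label values must lie in [0, 1]")
  TRUE
})

#' Named anatomical landmarks in world coordinates
#'
#' Landmarks live in world mm so they survive resampling and cropping without
#' re-annotation. Kinds follow the anatomy driving the evaluation: vessel
#' bifurcations, plaque/lesion positions, or generic points.
#'
#' @slot points data.frame with columns \code{name} (unique), \code{x},
#'   \code{y}, \code{z} (world mm) and \code{kind}
#'   (bifurcation | plaque | generic).
#' @exportClass LandmarkSet
setClass("LandmarkSet", slots = c(points = "data.frame"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  need <- c("name", "x", "y", "z", "kind")
  if (!all(need %in% names(p))) return("points needs name, x, y, z, kind")
  if (anyDuplicated(p$name)) return("landmark names must be unique")
  if (nrow(p) && any(!is.finite(as.matrix(p[, c("x", "y", "z")]))))
    return("landmark coordinates must be finite")
  if (nrow(p) && !all(p$kind %in% c("bifurcation", "plaque", "generic")))
    return("kind must be bifurcation, plaque or generic")
  TRUE
})

#' Dense displacement vector field
#'
#' A per-voxel 3-vector u(x) on the fixed grid, in voxel units, defining the
#' transform T(x) = x + u(x) that maps fixed-grid positions into the moving
#' image. Conversion to mm happens only inside metrics.
#'
#' @slot vectors 4D numeric array, dim (n1, n2, n3, 3).
#' @slot spacing numeric(3) mm per voxel of the fixed grid.
#' @slot origin numeric(3) world origin of the fixed grid.
#' @exportClass DisplacementField
setClass("DisplacementField",
  slots = c(vectors = "array", spacing = "numeric", origin = "numeric"),
  prototype = list(vectors = array(0, c(1, 1, 1, 3)), spacing = c(1, 1, 1),
                   origin = c(0, 0, 0)))

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4D array with 3 components in dimension 4")
  if (any(!is.finite(object@vectors))) return("field components must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  TRUE
})

#' A fixed/moving registration pair
#'
#' Bundles the fixed and moving volumes with their lumen labels, landmark
#' sets, an optional ground-truth displacement field (synthetic data), and a
#' patient/group identifier used for leakage-free cross-validation splits.
#' Fixed and moving spacings must agree; grid extents may differ per axis
#' (the cross-scale case).
#'
#' @exportClass RegistrationPair
setClass("RegistrationPair",
  slots = c(fixed = "ImageVolume", moving = "ImageVolume",
            fixedLabel = "ANY", movingLabel = "ANY",
            fixedLandmarks = "ANY", movingLandmarks = "ANY",
            gtDvf = "ANY", groupId = "character"))

setValidity("RegistrationPair", function(object) {
  if (max(abs(object@fixed@spacing - object@moving@spacing)) > 1e-6)
    return("fixed and moving spacings must be equal")
  chk <- function(lab, vol, what) {
    if (!is.null(lab)) {
      if (!is(lab, "LabelVolume")) return(paste(what, "must be a LabelVolume"))
      if (!identical(dim(lab@data), dim(vol@data)))
        return(paste(what, "extents must match its volume"))
    }
    NULL
  }
  m <- chk(object@fixedLabel, object@fixed, "fixedLabel")
  if (!is.null(m)) return(m)
  m <- chk(object@movingLabel, object@moving, "movingLabel")
  if (!is.null(m)) return(m)
  if (!is.null(object@gtDvf) && !is(object@gtDvf, "DisplacementField"))
    return("gtDvf must be a DisplacementField or NULL")
  if (length(object@groupId) != 1L) return("groupId must be a single string")
  TRUE
})

#' Discrete normalized Gaussian kernel
#'
#' Taps of exp(-x^2 / (2 sigma^2)) sampled at integer offsets
#' x in [-3 sigma, 3 sigma], normalized to unit sum. sigma = 0 marks the
#' identity (no smoothing).
#'
#' @slot sigma non-negative integer standard deviation, voxel units.
#' @slot taps numeric vector of kernel weights, symmetric, summing to 1.
#' @slot offsets integer offsets the taps are sampled at.
#' @exportClass GaussianKernel
setClass("GaussianKernel",
  slots = c(sigma = "numeric", taps = "numeric", offsets = "integer"))

setValidity("GaussianKernel", function(object) {
  if (object@sigma < 0) return("sigma must be non-negative")
  if (length(object@taps) != length(object@offsets))
    return("taps and offsets must have equal length")
  if (abs(sum(object@taps) - 1) > 1e-10) return("taps must sum to 1")
  TRUE
})

#' Siamese 3D U-Net registration network
#'
#' Two weight-shared down-sampling encoders (fixed and moving branches), a
#' feature-level zero-padding module that aligns moving-branch feature
#' extents to the fixed branch, and a single up-sampling decoder emitting a
#' dense 3-channel displacement field on the fixed grid.
#'
#' @slot params named list of weight/bias arrays.
#' @slot config network configuration list, see \code{\link{networkConfig}}.
#' @exportClass SiameseUNet
setClass("SiameseUNet", slots = c(params = "list", config = "list"))

## ------------------------------------------------------------------ generics

#' @export
setGeneric("extents", function(x) standardGeneric("extents"))
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @describeIn ImageVolume grid extents (voxels per axis)
#' @export
setMethod("extents", "ImageVolume", function(x) dim(x@data))
#' @export
setMethod("extents", "DisplacementField", function(x) dim(x@vectors)[1:3])
#' @describeIn ImageVolume voxel spacing in mm
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)
#' @describeIn ImageVolume world origin in mm
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)
#' @describeIn ImageVolume the raw 3D array
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)

#' Displacement vectors as a 4D array
#' @param x a DisplacementField
#' @return numeric array, dim (n1, n2, n3, 3), voxel units
#' @export
dvfVectors <- function(x) {
  stopifnot(is(x, "DisplacementField"))
  x@vectors
}

#' Landmark table
#' @param x a LandmarkSet
#' @return data.frame with name, x, y, z (mm), kind
#' @export
landmarkTable <- function(x) {
  stopifnot(is(x, "LandmarkSet"))
  x@points
}

#' Whether a label map is strictly binary
#' @param x a LabelVolume
#' @export
isBinary <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  all(x@data == 0 | x@data == 1)
}

## -------------------------------------------------------------- constructors

#' Create an ImageVolume
#' @param data 3D numeric array
#' @param spacing mm per voxel, length 1 (isotropic) or 3
#' @param origin world mm of voxel (0,0,0)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a LabelVolume
#' @inheritParams ImageVolume
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("LabelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a LandmarkSet
#' @param name character vector of unique names
#' @param coords n x 3 matrix of world mm coordinates
#' @param kind landmark kinds, recycled
#' @export
LandmarkSet <- function(name = character(), coords = matrix(0, 0, 3),
                        kind = "generic") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  new("LandmarkSet", points = data.frame(
    name = as.character(name), x = coords[, 1], y = coords[, 2],
    z = coords[, 3], kind = rep_len(as.character(kind), length(name)),
    stringsAsFactors = FALSE))
}

#' Create a DisplacementField
#' @param vectors 4D array, dim (n1, n2, n3, 3), voxel units
#' @param spacing mm per voxel of the fixed grid
#' @param origin world origin of the fixed grid
#' @export
DisplacementField <- function(vectors, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a RegistrationPair
#' @param fixed,moving ImageVolume
#' @param fixedLabel,movingLabel LabelVolume or NULL
#' @param fixedLandmarks,movingLandmarks LandmarkSet or NULL
#' @param gtDvf ground-truth DisplacementField or NULL
#' @param groupId patient/group identifier for split grouping
#' @export
RegistrationPair <- function(fixed, moving, fixedLabel = NULL,
                             movingLabel = NULL, fixedLandmarks = NULL,
                             movingLandmarks = NULL, gtDvf = NULL,
                             groupId = "g1") {
  new("RegistrationPair", fixed = fixed, moving = moving,
      fixedLabel = fixedLabel, movingLabel = movingLabel,
      fixedLandmarks = fixedLandmarks, movingLandmarks = movingLandmarks,
      gtDvf = gtDvf, groupId = as.character(groupId))
}

## ---------------------------------------------------------------------- show

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("%s %s, spacing %s mm, origin (%s) mm\n", class(object),
              paste(dim(object@data), collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
  invisible(object)
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet with %d point(s)\n", nrow(object@points)))
  if (nrow(object@points)) print(utils::head(object@points, 10))
  invisible(object)
})

setMethod("show", "DisplacementField", function(object) {
  m <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat(sprintf("DisplacementField %s, spacing %s mm, |u| max %.3f mean %.3f voxels\n",
              paste(dim(object@vectors)[1:3], collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              max(m), mean(m)))
  invisible(object)
})

setMethod("show", "RegistrationPair", function(object) {
  cat(sprintf("RegistrationPair [group %s]\n  fixed : %s\n  moving: %s\n",
              object@groupId, paste(dim(object@fixed@data), collapse = "x"),
              paste(dim(object@moving@data), collapse = "x")))
  cat(sprintf("  labels: %s, landmarks: %s, ground-truth DVF: %s\n",
              if (is.null(object@fixedLabel)) "none" else "yes",
              if (is.null(object@fixedLandmarks)) "none" else
                nrow(object@fixedLandmarks@points),
              if (is.null(object@gtDvf)) "none" else "yes"))
  invisible(object)
})

setMethod("show", "GaussianKernel", function(object) {
  cat(sprintf("GaussianKernel sigma=%g with %d tap(s)\n", object@sigma,
              length(object@taps)))
  invisible(object)
})

setMethod("show", "SiameseUNet", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cfg <- object@config
  cat(sprintf(
    "SiameseUNet: %d level(s), base %d channels, first kernel %d, %s parameters\n",
    cfg$levels, cfg$baseChannels, cfg$firstKernel, format(np, big.mark = ",")))
  cat(sprintf("  label input channels: %s, pad mode: %s\n",
              ifelse(isTRUE(cfg$useLabelChannels), "on", "off"), cfg$padMode))
  invisible(object)
})
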