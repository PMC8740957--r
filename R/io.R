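## NIfTI, landmark-table and manifest I/O.
##
## Volumes and labels travel as NIfTI-1 (.nii/.nii.gz); displacement fields as
## 4D NIfTI with the three components in the 4th dimension (voxel units, noted
## in the header description); landmarks as a plain-text table.

.asCanonical <- function(img) {
  # Normalize axis order to RAS when the file carries a usable xform, so that
  # volumes from differently-oriented acquisitions land in one axis convention.
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && !is.null(attr(xf, "code")) &&
      attr(xf, "code") > 0 && RNifti::orientation(img) != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  img
}

.imgGeometry <- function(img) {
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && !is.null(attr(xf, "code")) &&
      attr(xf, "code") > 0) {
    org <- xf[1:3, 4]
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))   # xform is authoritative when set
  }
  list(spacing = abs(as.numeric(sp)), origin = as.numeric(org))
}

#' Read a 3D volume (and optionally its label map) from NIfTI
#'
#' Axis order is normalized to a single canonical (RAS) convention on load
#' when the file provides an orientation. The label grid must match the
#' volume grid exactly.
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @param labelPath optional NIfTI label file on the same grid
#' @return an \linkS4class{ImageVolume}, or a list with elements
#'   \code{volume} and \code{label} when \code{labelPath} is given
#' @export
readVolume <- function(path, labelPath = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- .asCanonical(RNifti::readNifti(path))
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)), "D: ", path)
  g <- .imgGeometry(img)
  v <- ImageVolume(a, spacing = g$spacing, origin = g$origin)
  if (is.null(labelPath)) return(v)
  limg <- .asCanonical(RNifti::readNifti(labelPath))
  la <- unclass(limg)
  attributes(la) <- list(dim = dim(limg))
  if (!identical(dim(la), dim(a)))
    stop(sprintf("label extents (%s) do not match volume extents (%s)",
                 paste(dim(la), collapse = "x"), paste(dim(a), collapse = "x")))
  lg <- .imgGeometry(limg)
  list(volume = v, label = LabelVolume(la, spacing = lg$spacing,
                                       origin = lg$origin))
}

.writeNiftiArray <- function(a, spacing, origin, path, description = NULL) {
  img <- RNifti::asNifti(a)
  nd <- length(dim(a))
  RNifti::pixdim(img) <- c(spacing[1:3], rep(1, max(0L, nd - 3L)))
  aff <- rbind(cbind(diag(spacing[1:3]), origin[1:3]), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  if (!is.null(description)) img$descrip <- description
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume or label map to NIfTI
#' @param v ImageVolume or LabelVolume
#' @param path output file (.nii or .nii.gz)
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "ImageVolume"))
  .writeNiftiArray(v@data, v@spacing, v@origin, path)
}

#' Read a displacement field from 4D NIfTI
#' @param path NIfTI file with 3 components in the 4th dimension
#' @return a \linkS4class{DisplacementField} (voxel-unit convention)
#' @export
readDvf <- function(path) {
  img <- RNifti::readNifti(path)
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("expected a 4D NIfTI with 3 components: ", path)
  g <- .imgGeometry(img)
  DisplacementField(a, spacing = g$spacing, origin = g$origin)
}

#' Write a displacement field as 4D NIfTI
#' @param dvf DisplacementField
#' @param path output file
#' @export
writeDvf <- function(dvf, path) {
  stopifnot(is(dvf, "DisplacementField"))
  .writeNiftiArray(dvf@vectors, dvf@spacing, dvf@origin, path,
                   description = "displacement u(x), voxel units, fixed grid")
}

#' Read landmarks from a plain-text table
#'
#' One landmark per line: \code{name x_mm y_mm z_mm kind}, whitespace
#' separated; lines starting with \code{#} are comments.
#'
#' @param path text file
#' @export
readLandmarkSet <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(LandmarkSet())
  f <- do.call(rbind, strsplit(ln, "[[:space:]]+"))
  if (ncol(f) < 5L) stop("landmark lines need: name x y z kind")
  LandmarkSet(name = f[, 1],
              coords = matrix(as.numeric(f[, 2:4]), ncol = 3),
              kind = f[, 5])
}

#' Write landmarks as a plain-text table
#' @param lms LandmarkSet
#' @param path output file
#' @export
writeLandmarkSet <- function(lms, path) {
  stopifnot(is(lms, "LandmarkSet"))
  p <- lms@points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# name x_mm y_mm z_mm kind", con)
  if (nrow(p))
    writeLines(sprintf("%s %.9g %.9g %.9g %s", p$name, p$x, p$y, p$z, p$kind),
               con)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV listing registration pairs and their files, with
#' columns \code{pair_id}, \code{group_id}, \code{fixed}, \code{fixed_label},
#' \code{fixed_landmarks}, \code{moving}, \code{moving_label},
#' \code{moving_landmarks}, \code{gt_dvf} (paths relative to the manifest
#' location; empty where absent).
#'
#' @param path manifest CSV
#' @param load if TRUE, load every pair into a list of
#'   \linkS4class{RegistrationPair}
#' @return the manifest data.frame, or a list of pairs when \code{load}
#' @export
readManifest <- function(path, load = FALSE) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!load) return(mf)
  base <- dirname(path)
  rel <- function(p) if (is.na(p) || !nzchar(p)) NULL else file.path(base, p)
  lapply(seq_len(nrow(mf)), function(i) {
    r <- mf[i, ]
    fx <- readVolume(rel(r$fixed), rel(r$fixed_label))
    mv <- readVolume(rel(r$moving), rel(r$moving_label))
    fl <- ml <- NULL
    if (is.list(fx)) { fl <- fx$label; fx <- fx$volume }
    if (is.list(mv)) { ml <- mv$label; mv <- mv$volume }
    flm <- if (!is.null(rel(r$fixed_landmarks)))
      readLandmarkSet(rel(r$fixed_landmarks))
    mlm <- if (!is.null(rel(r$moving_landmarks)))
      readLandmarkSet(rel(r$moving_landmarks))
    gt <- if (!is.null(rel(r$gt_dvf))) readDvf(rel(r$gt_dvf))
    RegistrationPair(fx, mv, fixedLabel = fl, movingLabel = ml,
                     fixedLandmarks = flm, movingLandmarks = mlm,
                     gtDvf = gt, groupId = r$group_id)
  })
}
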