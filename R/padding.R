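## The cross-scale feature-alignment module.
##
## Fixed and moving inputs of different grid sizes give encoder features of
## different extents at every level. Zero-value padding applied to the
## moving branch's features -- strictly between encoder and decoder, never to
## the raw inputs -- brings each moving feature map to the extents of its
## fixed-branch counterpart, so one decoder can fuse both branches. Zero fill
## keeps the original feature content untouched and adds nothing where the
## anatomy of interest rarely sits (image borders).

#' Compute per-axis zero-padding amounts
#'
#' Returns the (before, after) pad cells per axis that grow \code{source}
#' extents to \code{target} extents. \code{symmetric} splits the difference
#' across both edges, placing the extra cell of an odd difference on the
#' trailing edge; \code{leading}/\code{trailing} put the whole difference on
#' one edge. Padding never crops: every target extent must be >= the source
#' extent.
#'
#' @param source,target integer extent triples
#' @param mode "symmetric", "leading" or "trailing"; recycled to 3 axes
#' @return 3x2 integer matrix with columns \code{before}, \code{after}
#' @export
computePadSpec <- function(source, target, mode = "symmetric") {
  source <- as.integer(source); target <- as.integer(target)
  stopifnot(length(source) == 3L, length(target) == 3L)
  mode <- rep_len(match.arg(mode, c("symmetric", "leading", "trailing"),
                            several.ok = TRUE), 3L)
  d <- target - source
  if (any(d < 0L))
    stop("target extents must be >= source extents on every axis ",
         "(padding never crops); offending axis ", which(d < 0L)[1])
  before <- integer(3L); after <- integer(3L)
  for (a in 1:3) {
    if (mode[a] == "symmetric") {
      before[a] <- d[a] %/% 2L
      after[a] <- d[a] - before[a]     # odd difference: extra cell trails
    } else if (mode[a] == "leading") {
      before[a] <- d[a]
    } else {
      after[a] <- d[a]
    }
  }
  m <- cbind(before = before, after = after)
  rownames(m) <- c("x", "y", "z")
  m
}

#' Apply zero-value padding to a feature grid
#'
#' Accepts a 3D grid or a channel-first 4D feature grid (channels, x, y, z).
#' New cells are exactly zero; original values keep their order, shifted by
#' the leading pad; the channel count is unchanged.
#'
#' @param f numeric array, 3D or 4D channel-first
#' @param spec 3x2 pad matrix from \code{\link{computePadSpec}}
#' @export
padFeatures <- function(f, spec) {
  spec <- matrix(as.integer(spec), ncol = 2)
  if (any(spec < 0L)) stop("pad amounts must be non-negative")
  nd <- length(dim(f))
  if (!nd %in% c(3L, 4L)) stop("feature grid must be 3D or 4D (channel-first)")
  sp <- dim(f)[if (nd == 4L) 2:4 else 1:3]
  out <- sp + spec[, 1] + spec[, 2]
  ix <- lapply(1:3, function(a) seq.int(spec[a, 1] + 1L, spec[a, 1] + sp[a]))
  if (nd == 3L) {
    g <- array(0, out)
    g[ix[[1]], ix[[2]], ix[[3]]] <- f
  } else {
    g <- array(0, c(dim(f)[1], out))
    g[, ix[[1]], ix[[2]], ix[[3]]] <- f
  }
  g
}

# inverse of padFeatures for gradients: slice the padded region back out
.unpadFeatures <- function(g, spec, nd = length(dim(g))) {
  spec <- matrix(as.integer(spec), ncol = 2)
  sp <- dim(g)[if (nd == 4L) 2:4 else 1:3] - spec[, 1] - spec[, 2]
  ix <- lapply(1:3, function(a) seq.int(spec[a, 1] + 1L, spec[a, 1] + sp[a]))
  if (nd == 3L) g[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  else g[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}
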