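## Training objective: soft Dice on anatomical labels, its multi-scale
## Gaussian-smoothed variant (GDSC), a displacement smoothness penalty, and
## their analytic gradients.
##
## Plain soft Dice has gradient magnitude 2 g^2 / (p + g)^2 with respect to a
## single soft-label entry: when the labels are sparse or barely overlap the
## denominator is tiny and the gradient blows up, destabilising training.
## Smoothing both labels with a bank of Gaussian kernels before the overlap
## spreads label mass over space, bounds the per-voxel gradient and gives the
## optimiser long-range pull; averaging over scales keeps the sharp term in
## play so fine detail is not lost.

.asLabelArray <- function(x) {
  if (is(x, "LabelVolume") || is(x, "ImageVolume")) x@data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a LabelVolume or a 3D array")
}

#' Discrete normalized Gaussian kernel
#'
#' Taps proportional to exp(-x^2 / (2 sigma^2)) at integer offsets
#' x = -3 sigma .. 3 sigma (6 sigma + 1 taps), divided by their sum.
#' sigma = 0 yields the identity kernel: smoothing with it is a no-op.
#'
#' @param sigma non-negative integer standard deviation (voxel units)
#' @return a \linkS4class{GaussianKernel}
#' @export
gaussianKernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0 || sigma != round(sigma))
    stop("sigma must be a single non-negative integer")
  sigma <- as.numeric(sigma)
  if (sigma == 0)
    return(new("GaussianKernel", sigma = 0, taps = 1, offsets = 0L))
  off <- seq.int(-3L * sigma, 3L * sigma)
  raw <- exp(-off^2 / (2 * sigma^2))
  new("GaussianKernel", sigma = sigma, taps = raw / sum(raw),
      offsets = as.integer(off))
}

# separable 3D smoothing of a plain array; zero extension at the boundary
.smoothArray <- function(a, kern) {
  if (kern@sigma == 0) return(a)
  d <- dim(a)
  for (ax in 0:2) a <- array(c_sepconv1(a, d, kern@taps, ax), d)
  a
}

#' Smooth a label map with a Gaussian kernel
#'
#' Separable 1D convolution along each axis with zero extension beyond the
#' grid. The identity kernel (sigma 0) returns the input unchanged; total
#' label mass is conserved except for leakage across the boundary.
#'
#' @param l LabelVolume (or 3D array)
#' @param k GaussianKernel, or a non-negative integer sigma
#' @return object of the same type as \code{l}
#' @export
smoothLabel <- function(l, k) {
  if (is.numeric(k)) k <- gaussianKernel(k)
  stopifnot(is(k, "GaussianKernel"))
  a <- .smoothArray(.asLabelArray(l), k)
  if (is(l, "LabelVolume")) initialize(l, data = pmin(pmax(a, 0), 1)) else a
}

#' Soft Dice loss
#'
#' \code{1 - 2 sum(p g) / (sum(p) + sum(g) + epsilon)} over all voxels.
#' Zero for perfectly overlapping labels, one for disjoint ones.
#'
#' @param p,g label maps (LabelVolume or 3D array) with equal extents;
#'   conventionally p is the warped moving label and g the fixed label
#' @param epsilon denominator stabilizer (guards empty labels)
#' @param gradient if TRUE also return the analytic gradient with respect
#'   to every entry of p
#' @return the loss, or \code{list(value, gradient)} when \code{gradient}
#' @export
dscLoss <- function(p, g, epsilon = 1e-6, gradient = FALSE) {
  pa <- .asLabelArray(p); ga <- .asLabelArray(g)
  if (!identical(dim(pa), dim(ga)))
    stop(sprintf("label extents differ: %s vs %s",
                 paste(dim(pa), collapse = "x"),
                 paste(dim(ga), collapse = "x")))
  S <- sum(pa) + sum(ga) + epsilon
  num <- 2 * sum(pa * ga)
  val <- 1 - num / S
  if (!gradient) return(val)
  grad <- -(2 * ga) / S + num / S^2
  list(value = val, gradient = grad)
}

#' Closed-form Dice gradient magnitude for a single label entry
#'
#' For a one-entry soft label pair the derivative of the Dice loss with
#' respect to p has magnitude \code{2 g^2 / (p + g)^2}. The formula is used
#' as an oracle to validate the implemented gradients and to exhibit the
#' small-denominator blow-up that motivates Gaussian-smoothed Dice: as
#' p + g shrinks the magnitude grows without bound.
#'
#' @param p,g scalar soft-label values with p + g > 0
#' @export
diceGradientOracle <- function(p, g) {
  stopifnot(is.numeric(p), is.numeric(g), length(p) == length(g))
  if (any(p + g <= 0))
    stop("p + g must be positive (the degenerate case is exactly the ",
         "instability Gaussian smoothing addresses)")
  2 * g^2 / (p + g)^2
}

#' Multi-scale Gaussian-smoothed Dice (GDSC) loss
#'
#' Both labels are smoothed with a Gaussian kernel for every sigma in
#' \code{sigmaSet}; the per-scale soft Dice overlaps are averaged and
#' subtracted from one:
#' \code{1 - (1/Z) sum_z 2 sum(p_z g_z) / (sum(p_z) + sum(g_z) + epsilon)}.
#' With \code{sigmaSet = 0} this reduces exactly to \code{\link{dscLoss}}.
#'
#' @inheritParams dscLoss
#' @param sigmaSet ordered set of non-negative integer smoothing scales
#' @param gSmoothed optional precomputed list of smoothed g arrays (one per
#'   sigma), an optimization for training loops where g is constant
#' @export
gdscLoss <- function(p, g, sigmaSet = c(0, 1, 2, 4, 8), epsilon = 1e-6,
                     gradient = FALSE, gSmoothed = NULL) {
  if (!length(sigmaSet)) stop("sigmaSet must contain at least one scale")
  pa <- .asLabelArray(p); ga <- .asLabelArray(g)
  if (!identical(dim(pa), dim(ga)))
    stop(sprintf("label extents differ: %s vs %s",
                 paste(dim(pa), collapse = "x"),
                 paste(dim(ga), collapse = "x")))
  Z <- length(sigmaSet)
  kerns <- lapply(sigmaSet, gaussianKernel)
  overlap <- numeric(Z)
  grad <- if (gradient) array(0, dim(pa))
  for (i in seq_len(Z)) {
    pz <- .smoothArray(pa, kerns[[i]])
    gz <- if (!is.null(gSmoothed)) gSmoothed[[i]]
          else .smoothArray(ga, kerns[[i]])
    S <- sum(pz) + sum(gz) + epsilon
    num <- 2 * sum(pz * gz)
    overlap[i] <- num / S
    if (gradient) {
      dOdpz <- (2 * gz) / S - num / S^2
      grad <- grad - .smoothArray(dOdpz, kerns[[i]]) / Z
    }
  }
  val <- 1 - mean(overlap)
  if (!gradient) val else list(value = val, gradient = grad)
}

# forward difference along an axis, zero at the trailing face
.fdiff <- function(a, ax) {
  d <- dim(a); n <- d[ax]
  idx <- rep(list(quote(expr = )), 3)
  hi <- idx; hi[[ax]] <- seq_len(n - 1) + 1L
  lo <- idx; lo[[ax]] <- seq_len(n - 1)
  out <- array(0, d)
  asn <- lo
  out <- do.call(`[<-`, c(list(out), asn, list(
    do.call(`[`, c(list(a), hi, list(drop = FALSE))) -
    do.call(`[`, c(list(a), lo, list(drop = FALSE))))))
  out
}

# adjoint of .fdiff: (D^T v)(x) = v(x - e) - v(x), with the boundary rows of
# v already zero by construction
.fdiffAdj <- function(v, ax) {
  d <- dim(v); n <- d[ax]
  idx <- rep(list(quote(expr = )), 3)
  hi <- idx; hi[[ax]] <- seq_len(n - 1) + 1L
  lo <- idx; lo[[ax]] <- seq_len(n - 1)
  out <- -v
  shift <- array(0, d)
  shift <- do.call(`[<-`, c(list(shift), hi, list(
    do.call(`[`, c(list(v), lo, list(drop = FALSE))))))
  out + shift
}

# central second difference along an axis, zero at both faces (so affine
# fields are exactly unpenalized)
.cdiff2 <- function(a, ax) {
  d <- dim(a); n <- d[ax]
  idx <- rep(list(quote(expr = )), 3)
  mid <- idx; mid[[ax]] <- 2:(n - 1)
  hi <- idx; hi[[ax]] <- 3:n
  lo <- idx; lo[[ax]] <- 1:(n - 2)
  out <- array(0, d)
  do.call(`[<-`, c(list(out), mid, list(
    do.call(`[`, c(list(a), hi, list(drop = FALSE))) -
    2 * do.call(`[`, c(list(a), mid, list(drop = FALSE))) +
    do.call(`[`, c(list(a), lo, list(drop = FALSE))))))
}

# adjoint of .cdiff2: the same stencil with zero extension and no face
# zeroing (the input is already zero at the faces by construction)
.cdiff2Adj <- function(v, ax) {
  d <- dim(v); n <- d[ax]
  shift <- function(by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- idx; dst <- idx
    if (by == 1L) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
    else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
    out <- array(0, d)
    do.call(`[<-`, c(list(out), dst, list(
      do.call(`[`, c(list(v), src, list(drop = FALSE))))))
  }
  shift(1L) - 2 * v + shift(-1L)
}

#' Displacement-field smoothness penalty
#'
#' \code{gradient} variant (default): the mean over voxels of the Frobenius
#' norm of the forward-difference Jacobian of the field -- a first-order
#' penalty on how fast displacement vectors change between neighbours.
#' \code{bending} variant: the mean of squared second-order finite
#' differences (a bending-energy style penalty that leaves affine fields,
#' e.g. uniform scalings, unpenalized).
#'
#' @param dvf DisplacementField or a 4D (n1,n2,n3,3) array, voxel units
#' @param variant "gradient" or "bending"
#' @param gradient if TRUE also return the analytic gradient with respect to
#'   every field component
#' @export
smoothnessLoss <- function(dvf, variant = c("gradient", "bending"),
                           gradient = FALSE) {
  variant <- match.arg(variant)
  u <- if (is(dvf, "DisplacementField")) dvf@vectors else dvf
  if (!(is.array(u) && length(dim(u)) == 4L && dim(u)[4] == 3L))
    stop("expected a DisplacementField or (n1,n2,n3,3) array")
  d <- dim(u)[1:3]
  nvox <- prod(d)
  if (variant == "gradient") {
    diffs <- vector("list", 9L)            # component i, axis k
    sq <- array(0, d)
    for (i in 1:3) for (k in 1:3) {
      dd <- .fdiff(u[, , , i], k)
      diffs[[(i - 1) * 3 + k]] <- dd
      sq <- sq + dd^2
    }
    nrm <- sqrt(sq)
    val <- sum(nrm) / nvox
    if (!gradient) return(val)
    inv <- array(0, d)
    pos <- nrm > 0
    inv[pos] <- 1 / nrm[pos]               # subgradient 0 where the norm is 0
    g <- array(0, dim(u))
    for (i in 1:3) for (k in 1:3) {
      dL <- diffs[[(i - 1) * 3 + k]] * inv / nvox
      g[, , , i] <- g[, , , i] + .fdiffAdj(dL, k)
    }
    return(list(value = val, gradient = g))
  }
  # bending: central second differences per axis and component
  val <- 0
  g <- if (gradient) array(0, dim(u))
  for (i in 1:3) for (k in 1:3) {
    s <- .cdiff2(u[, , , i], k)
    val <- val + sum(s^2) / nvox
    if (gradient)
      g[, , , i] <- g[, , , i] + .cdiff2Adj(2 * s / nvox, k)
  }
  if (!gradient) val else list(value = val, gradient = g)
}

#' Combined registration objective
#'
#' \code{gdscLoss(p, g) + alpha * smoothnessLoss(dvf)}: label-overlap
#' similarity plus a weighted smoothness penalty on the displacement field.
#'
#' @inheritParams gdscLoss
#' @param dvf the displacement field being regularized
#' @param alpha smoothness weight (default 0.5)
#' @param variant smoothness variant, see \code{\link{smoothnessLoss}}
#' @return list with \code{value}, \code{gdsc} and \code{smooth} components
#' @export
totalLoss <- function(p, g, dvf, alpha = 0.5, sigmaSet = c(0, 1, 2, 4, 8),
                      epsilon = 1e-6, variant = "gradient") {
  lg <- gdscLoss(p, g, sigmaSet = sigmaSet, epsilon = epsilon)
  ls <- smoothnessLoss(dvf, variant = variant)
  list(value = lg + alpha * ls, gdsc = lg, smooth = ls)
}
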