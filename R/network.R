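## The Siamese 3D U-Net.
##
## Two encoders with shared weights (one parameter set used by both the
## fixed and the moving branch) extract multi-level features; the padding
## module zero-pads every moving-branch feature map -- bottleneck and skip
## features, never the raw inputs -- to the extents of its fixed-branch
## counterpart; a single decoder with skip connections from both branches
## up-samples back to the fixed grid and a final convolution reduces to the
## 3 components of the displacement field.
##
## Feature tensors are channel-first arrays (C, d1, d2, d3). Forward and
## backward passes are hand-chained over the Rcpp kernels; gradients from
## both branches accumulate into the one shared parameter set.

#' Network configuration
#'
#' @param levels encoder depth: number of 2x2x2 max-pooling steps (>= 1)
#' @param baseChannels channels after the first convolution; doubled per level
#' @param firstKernel kernel size of the first convolution (default 7, a wide
#'   receptive field on the raw volumes)
#' @param innerKernel kernel size of all other convolutions (default 3)
#' @param pool pooling factor (only 2 is supported)
#' @param useLabelChannels if TRUE each branch input is (image, label)
#'   stacked as 2 channels; if FALSE the image alone (labels then drive the
#'   loss only)
#' @param padMode padding placement mode per \code{\link{computePadSpec}}
#' @param upsampleMode "nearest" (nearest-neighbour up-sampling followed by
#'   convolution)
#' @param fieldSigma non-negative integer; the displacement head smooths the
#'   raw 3-channel output with an isotropic Gaussian of this standard
#'   deviation (voxels). Classical Gaussian field regularization: it keeps
#'   the predicted field spatially coherent where the overlap loss carries
#'   no signal (label interiors). 0 disables it.
#' @export
networkConfig <- function(levels = 3L, baseChannels = 16L, firstKernel = 7L,
                          innerKernel = 3L, pool = 2L,
                          useLabelChannels = TRUE, padMode = "symmetric",
                          upsampleMode = "nearest", fieldSigma = 1L) {
  stopifnot(levels >= 1L, baseChannels >= 1L, firstKernel %% 2 == 1,
            innerKernel %% 2 == 1, fieldSigma >= 0)
  if (pool != 2L) stop("only pool = 2 is supported")
  if (upsampleMode != "nearest") stop("only nearest up-sampling is supported")
  list(levels = as.integer(levels), baseChannels = as.integer(baseChannels),
       firstKernel = as.integer(firstKernel),
       innerKernel = as.integer(innerKernel), pool = 2L,
       useLabelChannels = isTRUE(useLabelChannels), padMode = padMode,
       upsampleMode = upsampleMode, fieldSigma = as.integer(fieldSigma))
}

# smoothing head: separable Gaussian over the spatial axes of each output
# channel; self-adjoint (symmetric kernel, zero extension), so the backward
# pass applies the same operator to the output gradient
.smoothField <- function(out, sigma) {
  if (is.null(sigma) || sigma == 0) return(out)
  k <- gaussianKernel(sigma)
  d <- dim(out)[2:4]
  for (c in 1:3) out[c, , , ] <- .smoothArray(array(out[c, , , ], d), k)
  out
}

.chanAt <- function(cfg, l) cfg$baseChannels * 2L^(l - 1L)

# parameter shapes for every convolution in the network
.paramShapes <- function(cfg) {
  L <- cfg$levels
  cin <- if (cfg$useLabelChannels) 2L else 1L
  k <- cfg$innerKernel
  cB <- cfg$baseChannels * 2L^L
  sh <- list(first = c(cfg$baseChannels, cin, rep(cfg$firstKernel, 3)))
  prev <- cfg$baseChannels
  for (l in seq_len(L)) {
    cl <- .chanAt(cfg, l)
    sh[[paste0("enc", l, ".c1")]] <- c(cl, prev, rep(k, 3))
    sh[[paste0("enc", l, ".c2")]] <- c(cl, cl, rep(k, 3))
    prev <- cl
  }
  sh[["bott.c1"]] <- c(cB, prev, rep(k, 3))
  sh[["bott.c2"]] <- c(cB, cB, rep(k, 3))
  above <- 2L * cB                       # concat of both branches' bottlenecks
  for (l in rev(seq_len(L))) {
    cl <- .chanAt(cfg, l)
    sh[[paste0("dec", l, ".c1")]] <- c(cl, above + 2L * cl, rep(k, 3))
    sh[[paste0("dec", l, ".c2")]] <- c(cl, cl, rep(k, 3))
    above <- cl
  }
  sh[["final"]] <- c(3L, cfg$baseChannels, rep(k, 3))
  sh
}

#' Build a Siamese U-Net
#'
#' Weights use He initialization; the final displacement-regression layer is
#' initialized to zero so an untrained network predicts the identity
#' transform -- the standard stable starting point for field regression.
#' The parameter count is independent of input extents (the network is fully
#' convolutional), and both branches reference the same parameter set.
#'
#' @param cfg a \code{\link{networkConfig}}
#' @param seed RNG seed for weight initialization
#' @return a \linkS4class{SiameseUNet}
#' @export
buildNetwork <- function(cfg = networkConfig(), seed = 1L) {
  sh <- .paramShapes(cfg)
  params <- .withSeed(seed, {
    lapply(sh, function(s) {
      fanIn <- prod(s[-1])
      W <- array(stats::rnorm(prod(s), sd = sqrt(2 / fanIn)), s)
      list(W = W, b = numeric(s[1]))
    })
  })
  params$final$W[] <- 0
  new("SiameseUNet", params = params, config = cfg)
}

## ----------------------------------------------------------- layer wrappers

# Leaky ReLU (slope 0.2): a small negative-side slope keeps gradient flowing
# through units an early update pushed negative. With narrow layers and no
# normalization, plain ReLU lets a single aggressive step kill a whole layer
# (all channels negative everywhere -> zero features and zero gradients for
# the rest of training); the leak makes that state recoverable.
.leakySlope <- 0.2

.convFw <- function(pb, X, relu = TRUE) {
  Y <- c_conv3_fw(X, dim(X), pb$W, dim(pb$W), pb$b)
  dim(Y) <- c(dim(pb$W)[1], dim(X)[2:4])
  if (relu) {
    neg <- Y < 0
    Y[neg] <- .leakySlope * Y[neg]
  }
  list(X = X, A = Y, relu = relu)
}

.convBw <- function(pb, cache, dA, needDx = TRUE) {
  if (cache$relu) {
    neg <- cache$A < 0
    dA[neg] <- .leakySlope * dA[neg]
  }
  r <- c_conv3_bw(cache$X, dim(cache$X), pb$W, dim(pb$W), dA, needDx)
  if (needDx) dim(r$dX) <- dim(cache$X)
  r
}

.concatC <- function(...) {
  parts <- list(...)
  sp <- dim(parts[[1]])[2:4]
  cs <- vapply(parts, function(p) dim(p)[1], 1L)
  out <- c_concat_c(parts, cs, prod(sp))
  dim(out) <- c(sum(cs), sp)
  out
}

.splitC <- function(g, sizes) {
  sp <- dim(g)[2:4]
  parts <- c_split_c(g, as.integer(sizes), prod(sp))
  for (i in seq_along(parts)) dim(parts[[i]]) <- c(sizes[i], sp)
  parts
}

## ------------------------------------------------------------ forward pass

.encoderFw <- function(params, cfg, x) {
  L <- cfg$levels
  cc <- list(first = .convFw(params$first, x))
  x <- cc$first$A
  skips <- vector("list", L)
  pools <- vector("list", L)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    c1 <- .convFw(params[[paste0("enc", l, ".c1")]], x)
    c2 <- .convFw(params[[paste0("enc", l, ".c2")]], c1$A)
    skips[[l]] <- c2$A
    p <- c_maxpool_fw(c2$A, dim(c2$A))
    x <- p$Y
    dim(x) <- c(dim(c2$A)[1], dim(c2$A)[2:4] %/% 2L)
    pools[[l]] <- list(idx = p$idx, inDim = dim(c2$A))
    enc[[l]] <- list(c1 = c1, c2 = c2)
  }
  b1 <- .convFw(params[["bott.c1"]], x)
  b2 <- .convFw(params[["bott.c2"]], b1$A)
  list(cc = cc, enc = enc, skips = skips, pools = pools,
       bott = list(c1 = b1, c2 = b2), bottom = b2$A)
}

.encoderBw <- function(params, cfg, ec, dskips, dbottom, add) {
  L <- cfg$levels
  r <- .convBw(params[["bott.c2"]], ec$bott$c2, dbottom)
  add("bott.c2", r)
  r <- .convBw(params[["bott.c1"]], ec$bott$c1, r$dX)
  add("bott.c1", r)
  d <- r$dX
  for (l in rev(seq_len(L))) {
    dX <- c_maxpool_bw(d, ec$pools[[l]]$idx, prod(ec$pools[[l]]$inDim))
    dim(dX) <- ec$pools[[l]]$inDim
    dX <- dX + dskips[[l]]
    r <- .convBw(params[[paste0("enc", l, ".c2")]], ec$enc[[l]]$c2, dX)
    add(paste0("enc", l, ".c2"), r)
    r <- .convBw(params[[paste0("enc", l, ".c1")]], ec$enc[[l]]$c1, r$dX)
    add(paste0("enc", l, ".c1"), r)
    d <- r$dX
  }
  r <- .convBw(params$first, ec$cc$first, d, needDx = FALSE)
  add("first", r)
  invisible(NULL)
}

.checkExtents <- function(cfg, extF, extM) {
  div <- 2L^cfg$levels
  for (a in 1:3) {
    if (extF[a] %% div != 0L)
      stop(sprintf("fixed extent %d on axis %d is not divisible by %d (pool^levels)",
                   extF[a], a, div))
    if (extM[a] %% div != 0L)
      stop(sprintf("moving extent %d on axis %d is not divisible by %d (pool^levels)",
                   extM[a], a, div))
    if (extM[a] > extF[a])
      stop(sprintf("moving extent %d exceeds fixed extent %d on axis %d; the fixed grid must be the larger-or-equal one",
                   extM[a], extF[a], a))
  }
  invisible(NULL)
}

# xF, xM: channel-first input tensors. Returns the raw (3, d...) output and,
# when train = TRUE, the caches needed for the backward pass.
.netForward <- function(params, cfg, xF, xM, train = FALSE) {
  .checkExtents(cfg, dim(xF)[2:4], dim(xM)[2:4])
  L <- cfg$levels
  eF <- .encoderFw(params, cfg, xF)
  eM <- .encoderFw(params, cfg, xM)
  padBott <- computePadSpec(dim(eM$bottom)[2:4], dim(eF$bottom)[2:4],
                            cfg$padMode)
  d <- .concatC(eF$bottom, padFeatures(eM$bottom, padBott))
  padSkip <- vector("list", L)
  dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up <- c_upsample_fw(d, dim(d))
    dim(up) <- c(dim(d)[1], 2L * dim(d)[2:4])
    padSkip[[l]] <- computePadSpec(dim(eM$skips[[l]])[2:4],
                                   dim(eF$skips[[l]])[2:4], cfg$padMode)
    cat3 <- .concatC(up, eF$skips[[l]], padFeatures(eM$skips[[l]], padSkip[[l]]))
    c1 <- .convFw(params[[paste0("dec", l, ".c1")]], cat3)
    c2 <- .convFw(params[[paste0("dec", l, ".c2")]], c1$A)
    dec[[l]] <- list(c1 = c1, c2 = c2, upC = dim(d)[1],
                     skipC = dim(eF$skips[[l]])[1], upDimIn = dim(d))
    d <- c2$A
  }
  fin <- .convFw(params$final, d, relu = FALSE)
  out <- .smoothField(fin$A, cfg$fieldSigma)
  if (!train) return(list(out = out))
  list(out = out, eF = eF, eM = eM, dec = dec, fin = fin,
       padBott = padBott, padSkip = padSkip,
       bottC = dim(eF$bottom)[1])
}

# dOut: gradient with respect to the raw (3, d...) output.
# Returns a named list of list(dW, db) matching the parameter set.
.netBackward <- function(params, cfg, fw, dOut) {
  L <- cfg$levels
  grads <- new.env(parent = emptyenv())
  add <- function(name, r) {
    cur <- grads[[name]]
    if (is.null(cur)) grads[[name]] <- list(dW = r$dW, db = r$db)
    else grads[[name]] <- list(dW = cur$dW + r$dW, db = cur$db + r$db)
  }
  dOut <- .smoothField(dOut, cfg$fieldSigma)   # self-adjoint smoothing head
  r <- .convBw(params$final, fw$fin, dOut)
  add("final", r)
  d <- r$dX
  dskipF <- vector("list", L)
  dskipM <- vector("list", L)
  for (l in seq_len(L)) {       # reverse of the decoder's L..1 order
    r <- .convBw(params[[paste0("dec", l, ".c2")]], fw$dec[[l]]$c2, d)
    add(paste0("dec", l, ".c2"), r)
    r <- .convBw(params[[paste0("dec", l, ".c1")]], fw$dec[[l]]$c1, r$dX)
    add(paste0("dec", l, ".c1"), r)
    sp <- .splitC(r$dX, c(fw$dec[[l]]$upC, fw$dec[[l]]$skipC, fw$dec[[l]]$skipC))
    dskipF[[l]] <- sp[[2]]
    dskipM[[l]] <- .unpadFeatures(sp[[3]], fw$padSkip[[l]], nd = 4L)
    dUp <- c_upsample_bw(sp[[1]], dim(sp[[1]]))
    dim(dUp) <- fw$dec[[l]]$upDimIn
    d <- dUp
  }
  sp <- .splitC(d, c(fw$bottC, fw$bottC))
  dbF <- sp[[1]]
  dbM <- .unpadFeatures(sp[[2]], fw$padBott, nd = 4L)
  .encoderBw(params, cfg, fw$eF, dskipF, dbF, add)
  .encoderBw(params, cfg, fw$eM, dskipM, dbM, add)
  as.list(grads)
}

## -------------------------------------------------------------- public API

.stackChannels <- function(vol, label, useLabels) {
  d <- dim(vol@data)
  if (useLabels) {
    if (is.null(label))
      stop("the network was configured with label input channels; ",
           "supply labels or set useLabelChannels = FALSE")
    x <- array(0, c(2L, d))
    x[1L, , , ] <- vol@data
    x[2L, , , ] <- label@data
  } else {
    x <- array(vol@data, c(1L, d))
  }
  x
}

#' Predict a displacement field for a fixed/moving pair
#'
#' Runs the Siamese U-Net forward. The output field always has the fixed
#' volume's extents -- for every admissible extent combination, including
#' cross-scale pairs where the moving grid is smaller -- with 3 components
#' in voxel units.
#'
#' @param net a \linkS4class{SiameseUNet}
#' @param fixed,moving ImageVolume (extents divisible by 2^levels; moving
#'   extents must not exceed fixed extents on any axis)
#' @param fixedLabel,movingLabel LabelVolume inputs when the network uses
#'   label channels
#' @return a \linkS4class{DisplacementField} on the fixed grid
#' @export
predictDvf <- function(net, fixed, moving, fixedLabel = NULL,
                       movingLabel = NULL) {
  stopifnot(is(net, "SiameseUNet"), is(fixed, "ImageVolume"),
            is(moving, "ImageVolume"))
  cfg <- net@config
  xF <- .stackChannels(fixed, fixedLabel, cfg$useLabelChannels)
  xM <- .stackChannels(moving, movingLabel, cfg$useLabelChannels)
  fw <- .netForward(net@params, cfg, xF, xM, train = FALSE)
  DisplacementField(aperm(fw$out, c(2, 3, 4, 1)), spacing = fixed@spacing,
                    origin = fixed@origin)
}

#' Save a network checkpoint
#'
#' Checkpoints are RDS files with a versioned payload: the network config,
#' parameters, optional optimizer state and metadata, and the RNG state (so
#' training can resume bit-for-bit).
#'
#' @param net SiameseUNet
#' @param path output file
#' @param optState optional optimizer state (from the training loop)
#' @param meta optional metadata list
#' @export
saveCheckpoint <- function(net, path, optState = NULL, meta = list()) {
  stopifnot(is(net, "SiameseUNet"))
  rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  saveRDS(list(format = "siamreg-checkpoint", version = 1L,
               config = net@config, params = net@params, opt = optState,
               meta = meta, rng = rng), path)
  invisible(path)
}

#' Load a network checkpoint
#' @param path checkpoint file written by \code{\link{saveCheckpoint}}
#' @return list with \code{net}, \code{opt}, \code{meta}, \code{rng}
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "siamreg-checkpoint"))
    stop("not a siamreg checkpoint: ", path)
  if (ck$version > 1L)
    stop("checkpoint version ", ck$version, " is newer than this package")
  list(net = new("SiameseUNet", params = ck$params, config = ck$config),
       opt = ck$opt, meta = ck$meta, rng = ck$rng)
}
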