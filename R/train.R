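## Weakly supervised training: Adam on the combined objective
## (multi-scale Gaussian-smoothed Dice on the warped moving label vs the
## fixed label, plus the weighted smoothness penalty), with grouped k-fold
## splitting and the command-line-facing register step.

#' Loss configuration
#'
#' @param sigmaSet ordered non-negative integer smoothing scales; the
#'   default bank \{0,1,2,4,8\} mixes the sharp Dice term with increasingly
#'   global smoothed terms
#' @param alpha smoothness regularization weight
#' @param smoothVariant "gradient" (first-order) or "bending" (second-order)
#' @param epsilon Dice denominator stabilizer
#' @export
lossConfig <- function(sigmaSet = c(0, 1, 2, 4, 8), alpha = 0.5,
                       smoothVariant = "gradient", epsilon = 1e-6) {
  stopifnot(length(sigmaSet) >= 1, alpha >= 0, epsilon > 0)
  list(sigmaSet = sigmaSet, alpha = alpha,
       smoothVariant = match.arg(smoothVariant, c("gradient", "bending")),
       epsilon = epsilon)
}

#' Training configuration
#'
#' Defaults follow the reference training regime: Adam with initial
#' learning rate 1e-4, 10,000 iterations, batch size 2, a checkpoint every
#' 15 iterations, 4 cross-validation folds. Scaled-down experiments override
#' iterations/learning rate explicitly.
#'
#' @param learningRate Adam learning rate
#' @param iterations optimizer steps
#' @param batchSize pairs per step; cross-scale pairs of unequal extents are
#'   processed as accumulated single-pair gradients (dense mixed-extent
#'   minibatches are impossible), so this is an effective batch size
#' @param checkpointInterval iterations between checkpoints
#' @param folds cross-validation folds
#' @param adamEpsilon Adam denominator offset. Label-overlap losses produce
#'   gradients spanning many orders of magnitude across parameters; the
#'   default 1e-5 keeps near-noise parameters from taking full-size
#'   sign steps (which destabilizes short schedules), while leaving
#'   well-measured gradients normalized
#' @param lrDecayFactor,lrDecayAt optional step decay: after
#'   \code{lrDecayAt} (a fraction of the total iterations) the learning
#'   rate is multiplied by \code{lrDecayFactor}. The default factor 1 keeps
#'   the rate constant; short schedules benefit from a late decay that
#'   settles the field once overlap is roughly recovered
#' @param warmupIters linear learning-rate warm-up over this many initial
#'   iterations. Adam's earliest steps are sign-like (second-moment
#'   statistics are still empty) and can push the zero-initialized
#'   displacement head into an oscillating trap around the identity
#'   transform; warming up while the moment estimates fill removes that
#'   failure mode
#' @param seed master RNG seed (initialization, sampling, augmentation)
#' @param augmentFlip double the training set with left/right-flipped copies
#'   before training
#' @param augmentAffine apply a random small affine to each sampled pair
#'   on the fly
#' @param loss a \code{\link{lossConfig}}
#' @param network a \code{\link{networkConfig}}
#' @export
trainConfig <- function(learningRate = 1e-4, iterations = 10000L,
                        batchSize = 2L, checkpointInterval = 15L,
                        folds = 4L, adamEpsilon = 1e-5,
                        lrDecayFactor = 1, lrDecayAt = 2 / 3,
                        warmupIters = 50L, seed = 1L,
                        augmentFlip = TRUE, augmentAffine = TRUE,
                        loss = lossConfig(), network = networkConfig()) {
  stopifnot(learningRate > 0, iterations >= 1, batchSize >= 1,
            checkpointInterval >= 1, folds >= 2, adamEpsilon > 0,
            lrDecayFactor > 0, lrDecayFactor <= 1,
            lrDecayAt > 0, lrDecayAt <= 1, warmupIters >= 0)
  list(learningRate = learningRate, iterations = as.integer(iterations),
       batchSize = as.integer(batchSize),
       checkpointInterval = as.integer(checkpointInterval),
       folds = as.integer(folds), adamEpsilon = adamEpsilon,
       lrDecayFactor = lrDecayFactor, lrDecayAt = lrDecayAt,
       warmupIters = as.integer(warmupIters), seed = as.integer(seed),
       augmentFlip = isTRUE(augmentFlip),
       augmentAffine = isTRUE(augmentAffine), loss = loss, network = network)
}

#' Grouped k-fold split
#'
#' Partitions the *groups* (patients), not the pairs: all pairs sharing a
#' group id land in the same side of every split, so left/right vessels of
#' one patient can never leak between training and test sets.
#'
#' @param pairs list of RegistrationPair, or a character vector of group ids
#' @param folds number of folds
#' @param seed shuffle seed
#' @return list of \code{folds} elements, each \code{list(train, test)} of
#'   pair indices
#' @export
groupedKFold <- function(pairs, folds = 4L, seed = 1L) {
  gids <- if (is.character(pairs)) pairs
          else vapply(pairs, function(p) p@groupId, "")
  ug <- unique(gids)
  if (length(ug) < folds)
    stop("fewer groups (", length(ug), ") than folds (", folds, ")")
  ug <- .withSeed(seed, sample(ug))
  fold <- rep(seq_len(folds), length.out = length(ug))
  lapply(seq_len(folds), function(f) {
    testGroups <- ug[fold == f]
    idx <- seq_along(gids)
    list(train = idx[!(gids %in% testGroups)],
         test = idx[gids %in% testGroups])
  })
}

# per-pair training tensors; the origin shift maps fixed-grid positions into
# the (possibly cropped) moving grid. The smoothed fixed labels g_z of the
# loss pyramid are constant across iterations and cached.
.pairTensors <- function(pr, cfg) {
  netCfg <- cfg$network
  list(
    xF = .stackChannels(pr@fixed, pr@fixedLabel, netCfg$useLabelChannels),
    xM = .stackChannels(pr@moving, pr@movingLabel, netCfg$useLabelChannels),
    movLab = pr@movingLabel@data,
    gArr = pr@fixedLabel@data,
    shift = (pr@fixed@origin - pr@moving@origin) / pr@moving@spacing,
    gPyramid = lapply(cfg$loss$sigmaSet, function(s)
      .smoothArray(pr@fixedLabel@data, gaussianKernel(s))))
}

# forward + loss + gradients for one pair: warp the moving label softly,
# evaluate the multi-scale smoothed Dice against the fixed label, chain the
# loss gradient back through the smoothing adjoints and the warp Jacobian
# into the field, add the smoothness gradient, and backpropagate through
# the network.
.trainStep <- function(params, cfg, tn) {
  netCfg <- cfg$network
  fw <- .netForward(params, netCfg, tn$xF, tn$xM, train = TRUE)
  odim <- dim(fw$out)[2:4]
  u <- aperm(fw$out, c(2, 3, 4, 1))
  uw <- u
  if (any(abs(tn$shift) > 1e-12))
    for (c in 1:3) uw[, , , c] <- uw[, , , c] + tn$shift[c]
  p <- array(c_warp(tn$movLab, dim(tn$movLab), uw, odim, 1L, 0L), odim)
  lg <- gdscLoss(p, tn$gArr, sigmaSet = cfg$loss$sigmaSet,
                 epsilon = cfg$loss$epsilon, gradient = TRUE,
                 gSmoothed = tn$gPyramid)
  dU <- array(c_warp_bw(tn$movLab, dim(tn$movLab), uw, odim, lg$gradient),
              c(odim, 3L))
  ls <- smoothnessLoss(u, variant = cfg$loss$smoothVariant, gradient = TRUE)
  dU <- dU + cfg$loss$alpha * ls$gradient
  grads <- .netBackward(params, netCfg, fw, aperm(dU, c(4, 1, 2, 3)))
  list(gdsc = lg$value, smooth = ls$value,
       total = lg$value + cfg$loss$alpha * ls$value, grads = grads)
}

.adamInit <- function(params) {
  list(t = 0L, m = lapply(params, function(p)
    list(W = array(0, dim(p$W)), b = numeric(length(p$b)))),
    v = lapply(params, function(p)
      list(W = array(0, dim(p$W)), b = numeric(length(p$b)))))
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[if (part == "W") "dW" else "db"]]
      st$m[[nm]][[part]] <- beta1 * st$m[[nm]][[part]] + (1 - beta1) * g
      st$v[[nm]][[part]] <- beta2 * st$v[[nm]][[part]] + (1 - beta2) * g^2
      upd <- lr * (st$m[[nm]][[part]] / c1) /
        (sqrt(st$v[[nm]][[part]] / c2) + eps)
      params[[nm]][[part]] <- params[[nm]][[part]] - upd
    }
  }
  list(params = params, state = st)
}

.meanValDsc <- function(params, cfg, valPairs) {
  net <- new("SiameseUNet", params = params, config = cfg$network)
  mean(vapply(valPairs, function(pr) {
    dvf <- predictDvf(net, pr@fixed, pr@moving, pr@fixedLabel, pr@movingLabel)
    dsc(pr@fixedLabel, warpVolume(pr@movingLabel, dvf, interp = "nearest"))
  }, 1))
}

#' Train the Siamese U-Net
#'
#' Minimizes the combined objective over the training pairs with Adam.
#' Every pair satisfies the network's divisibility constraint (checked
#' before training starts). Checkpoints are taken every
#' \code{checkpointInterval} iterations; when validation pairs are given the
#' returned network is the checkpoint with the best mean validation DSC,
#' otherwise the final one. Fixed seeds make runs bit-reproducible on one
#' machine, and a checkpoint stores the optimizer and RNG state so training
#' resumes exactly.
#'
#' @param pairs list of RegistrationPair (the training split)
#' @param cfg a \code{\link{trainConfig}}
#' @param validationPairs optional held-out pairs for checkpoint selection
#' @param checkpointDir optional directory for on-disk checkpoints
#' @param resumeFrom optional checkpoint path (or loaded checkpoint) to
#'   continue from
#' @param verbose print loss every few iterations
#' @return list with \code{net} (selected network), \code{finalNet},
#'   \code{log} (per-iteration loss data.frame), \code{valLog},
#'   \code{config}
#' @export
trainNetwork <- function(pairs, cfg = trainConfig(), validationPairs = NULL,
                         checkpointDir = NULL, resumeFrom = NULL,
                         verbose = FALSE) {
  stopifnot(length(pairs) >= 1)
  netCfg <- cfg$network
  for (pr in pairs)
    .checkExtents(netCfg, dim(pr@fixed@data), dim(pr@moving@data))
  if (cfg$augmentFlip)
    pairs <- c(pairs, lapply(pairs, augmentPair, mode = "lr_flip"))
  baseTensors <- lapply(pairs, .pairTensors, cfg = cfg)
  startIter <- 0L
  queue <- integer(0)    # balanced sampling: shuffled epochs over the pairs
  if (!is.null(resumeFrom)) {
    ck <- if (is.character(resumeFrom)) loadCheckpoint(resumeFrom) else resumeFrom
    params <- ck$net@params
    optState <- ck$opt
    startIter <- ck$meta$iter
    if (!is.null(ck$meta$queue)) queue <- ck$meta$queue
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, globalenv())
  } else {
    params <- buildNetwork(netCfg, seed = cfg$seed)@params
    optState <- .adamInit(params)
    set.seed(cfg$seed)
  }
  logRows <- vector("list", cfg$iterations - startIter)
  valLog <- list()
  bestVal <- -Inf
  bestParams <- params
  for (it in seq.int(startIter + 1L, cfg$iterations)) {
    nb <- min(cfg$batchSize, length(pairs))
    while (length(queue) < nb) queue <- c(queue, sample.int(length(pairs)))
    take <- queue[seq_len(nb)]
    queue <- queue[-seq_len(nb)]
    lrNow <- cfg$learningRate *
      (if (cfg$warmupIters > 0L) min(1, it / cfg$warmupIters) else 1) *
      (if (it > cfg$lrDecayAt * cfg$iterations) cfg$lrDecayFactor else 1)
    comp <- c(gdsc = 0, smooth = 0, total = 0)
    acc <- NULL
    for (j in take) {
      tn <- baseTensors[[j]]
      if (cfg$augmentAffine) {
        apr <- augmentPair(pairs[[j]], mode = "affine",
                           seed = sample.int(1e8, 1))
        tn <- .pairTensors(apr, cfg)
      }
      st <- .trainStep(params, cfg, tn)
      comp <- comp + c(st$gdsc, st$smooth, st$total) / length(take)
      if (is.null(acc)) acc <- st$grads
      else for (nm in names(acc)) {
        acc[[nm]]$dW <- acc[[nm]]$dW + st$grads[[nm]]$dW
        acc[[nm]]$db <- acc[[nm]]$db + st$grads[[nm]]$db
      }
    }
    for (nm in names(acc)) {
      acc[[nm]]$dW <- acc[[nm]]$dW / length(take)
      acc[[nm]]$db <- acc[[nm]]$db / length(take)
    }
    upd <- .adamStep(params, acc, optState, lrNow,
                     eps = if (is.null(cfg$adamEpsilon)) 1e-5
                           else cfg$adamEpsilon)
    params <- upd$params
    optState <- upd$state
    logRows[[it - startIter]] <- data.frame(
      iter = it, gdsc = comp[["gdsc"]], smooth = comp[["smooth"]],
      total = comp[["total"]])
    if (verbose && it %% 25L == 0L)
      message(sprintf("iter %d: total %.4f (gdsc %.4f, smooth %.4f)", it,
                      comp[["total"]], comp[["gdsc"]], comp[["smooth"]]))
    if (it %% cfg$checkpointInterval == 0L || it == cfg$iterations) {
      vd <- NA_real_
      if (!is.null(validationPairs)) {
        vd <- .meanValDsc(params, cfg, validationPairs)
        if (vd > bestVal) {
          bestVal <- vd
          bestParams <- params
        }
      } else {
        bestParams <- params
      }
      valLog[[length(valLog) + 1L]] <- data.frame(iter = it, valDsc = vd)
      if (!is.null(checkpointDir)) {
        dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
        saveCheckpoint(new("SiameseUNet", params = params, config = netCfg),
                       file.path(checkpointDir, sprintf("ckpt_%06d.rds", it)),
                       optState = optState,
                       meta = list(iter = it, valDsc = vd, queue = queue))
      }
    }
  }
  list(net = new("SiameseUNet", params = bestParams, config = netCfg),
       finalNet = new("SiameseUNet", params = params, config = netCfg),
       log = do.call(rbind, logRows), valLog = do.call(rbind, valLog),
       config = cfg)
}

#' Register one pair with a trained network
#'
#' Predicts the displacement field, warps the moving image (trilinear,
#' border-clamped) and its label (nearest, stays binary), optionally writes
#' the three outputs as NIfTI next to \code{outputPrefix}, and reports the
#' wall time.
#'
#' @param net SiameseUNet or path to a checkpoint file
#' @param fixed,moving ImageVolume
#' @param fixedLabel,movingLabel optional LabelVolume
#' @param outputPrefix optional path prefix for \code{_dvf.nii.gz},
#'   \code{_warped.nii.gz}, \code{_warped_label.nii.gz}
#' @param verbose print the elapsed wall time
#' @export
registerPair <- function(net, fixed, moving, fixedLabel = NULL,
                         movingLabel = NULL, outputPrefix = NULL,
                         verbose = TRUE) {
  if (is.character(net)) net <- loadCheckpoint(net)$net
  t0 <- proc.time()[["elapsed"]]
  dvf <- tryCatch(
    predictDvf(net, fixed, moving, fixedLabel, movingLabel),
    error = function(e)
      stop(conditionMessage(e),
           "\n(hint: crop the volumes, or pad them to extents divisible by ",
           2L^net@config$levels, ")", call. = FALSE))
  warped <- warpVolume(moving, dvf, interp = "trilinear", oob = "border")
  warpedLab <- if (!is.null(movingLabel))
    warpVolume(movingLabel, dvf, interp = "nearest", oob = "zero")
  secs <- proc.time()[["elapsed"]] - t0
  if (!is.null(outputPrefix)) {
    writeDvf(dvf, paste0(outputPrefix, "_dvf.nii.gz"))
    writeVolume(warped, paste0(outputPrefix, "_warped.nii.gz"))
    if (!is.null(warpedLab))
      writeVolume(warpedLab, paste0(outputPrefix, "_warped_label.nii.gz"))
  }
  if (verbose) message(sprintf("registered in %.2f s", secs))
  list(dvf = dvf, warpedImage = warped, warpedLabel = warpedLab,
       seconds = secs)
}
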