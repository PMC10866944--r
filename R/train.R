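#' Training configuration
#'
#' Defaults follow the published recipe: SGD with momentum 0.9, learning
#' rate 8e-3 (constant), batch size 16, shuffling after each epoch,
#' five case-level folds. Epochs scale down for desk-scale runs.
#'
#' @param lr learning rate
#' @param momentum SGD momentum
#' @param batch_size slices per batch
#' @param epochs training epochs per fold
#' @param folds number of cross-validation folds (>= 2)
#' @param seed global seed; per-epoch streams derive from it
#' @param augment an \code{\link{augmentConfig}} or NULL to disable
#' @param min_brain_fraction training-slice filter (see
#'   \code{\link{preprocessCase}})
#' @return a \code{trainConfig} list
#' @export
trainConfig <- function(lr = 8e-3, momentum = 0.9, batch_size = 16L,
                        epochs = 250L, folds = 5L, seed = 1L,
                        augment = augmentConfig(),
                        min_brain_fraction = 0.01) {
  stopifnot(lr > 0, batch_size >= 1, folds >= 2)
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), augment = augment,
                 min_brain_fraction = min_brain_fraction),
            class = "trainConfig")
}

#' Case-level k-fold split
#'
#' Deterministic under \code{seed}; validation sets are disjoint, differ
#' in size by at most one, and their union is the full cohort. Splitting
#' is at case level only, so no validation case ever contributes a
#' training slice.
#'
#' @param case_ids character vector of case identifiers
#' @param k number of folds
#' @param seed integer seed
#' @return list of length k: \code{train} / \code{validation} id vectors
#' @export
makeFolds <- function(case_ids, k, seed = 1L) {
  if (length(case_ids) < k)
    stop("fewer cases than folds")
  perm <- withSeed(seed, sample(case_ids))
  assign_fold <- rep_len(seq_len(k), length(perm))
  lapply(seq_len(k), function(f)
    list(train = perm[assign_fold != f],
         validation = perm[assign_fold == f]))
}

.sgdStep <- function(params, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- if (is.null(vel[[nm]])) -lr * g else momentum * vel[[nm]] - lr * g
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, vel = vel)
}

.sliceBatchArray <- function(slices, idx) {
  d <- dim(slices[[idx[1]]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], length(idx)))
  y <- array(0L, dim = c(d[1], d[2], length(idx)))
  for (i in seq_along(idx)) {
    x[, , , i] <- slices[[idx[i]]]$image
    y[, , i] <- slices[[idx[i]]]$label
  }
  list(x = x, y = y)
}

.batchLoss <- function(model, x, y, training = TRUE) {
  fw <- netForward(model, x, training = training, keep_cache = training)
  C <- model$cfg$num_classes
  yv <- .onehot(y, C)                               # [H, W, N, C]
  dim(yv) <- c(length(yv) / C, C)
  s <- aperm(fw$probs, c(1, 2, 4, 3))               # [H, W, N, C]
  dim(s) <- c(length(s) / C, C)
  lo <- overallLoss(s, yv, grad = training)
  out <- list(fw = fw, loss = lo)
  if (training) {
    dl <- lo$dlogits
    dim(dl) <- c(dim(x)[1], dim(x)[2], dim(x)[4], C)
    out$dlogits <- aperm(dl, c(1, 2, 4, 3))
  }
  out
}

#' Train one cross-validation fold
#'
#' Iterates all retained training slices once per epoch in shuffled order
#' (per-epoch seeds derive from the global seed and fold index), applies
#' on-the-fly augmentation, optimizes the combined generalized-dice +
#' cross-entropy objective with momentum SGD, and keeps the checkpoint
#' with the best mean validation region dice (ET/TC/WT average).
#'
#' @param fold_idx fold number (1-based), used for seed derivation
#' @param split one element of \code{\link{makeFolds}}
#' @param cases named list of preprocessed cases
#'   (\code{\link{preprocessCase}} outputs), names = case ids
#' @param model_cfg a \code{\link{modelConfig}}
#' @param train_cfg a \code{\link{trainConfig}}
#' @param verbose print per-epoch progress
#' @return list with \code{model} (best checkpoint), \code{last_model},
#'   \code{log} (per-step losses) and \code{val_log} (per-epoch
#'   validation dice)
#' @export
trainFold <- function(fold_idx, split, cases, model_cfg, train_cfg,
                      verbose = FALSE) {
  model <- buildModel(model_cfg, seed = deriveSeed(train_cfg$seed, 7L,
                                                  fold_idx))
  tr_slices <- list()
  for (id in split$train)
    tr_slices <- c(tr_slices,
                   extractAxialSlices(cases[[id]], training_only = TRUE))
  va_slices <- list()
  for (id in split$validation)
    va_slices <- c(va_slices,
                   extractAxialSlices(cases[[id]], training_only = TRUE))
  n <- length(tr_slices)
  stopifnot(n >= 1)
  vel <- list()
  log <- data.frame()
  val_log <- data.frame()
  best <- list(dice = -Inf, model = NULL)
  for (ep in seq_len(train_cfg$epochs)) {
    ep_seed <- deriveSeed(train_cfg$seed, fold_idx, ep)
    order_idx <- withSeed(ep_seed, sample(n))
    nb <- ceiling(n / train_cfg$batch_size)
    for (bi in seq_len(nb)) {
      idx <- order_idx[((bi - 1) * train_cfg$batch_size + 1):
                         min(bi * train_cfg$batch_size, n)]
      batch_slices <- lapply(seq_along(idx), function(i) {
        sl <- tr_slices[[idx[i]]]
        if (!is.null(train_cfg$augment)) {
          sl <- augmentPair(sl, train_cfg$augment,
                            seed = deriveSeed(ep_seed, bi, i))$pair
        }
        sl
      })
      d <- dim(batch_slices[[1]]$image)
      x <- array(0, dim = c(d, length(idx)))
      y <- array(0L, dim = c(d[1], d[2], length(idx)))
      for (i in seq_along(batch_slices)) {
        x[, , , i] <- batch_slices[[i]]$image
        y[, , i] <- batch_slices[[i]]$label
      }
      bl <- .batchLoss(model, x, y, training = TRUE)
      if (!is.finite(bl$loss$L_Overall))
        stop(sprintf(
          "NaN/Inf loss at fold %d epoch %d batch %d (batch mean %.4g, sd %.4g)",
          fold_idx, ep, bi, mean(x), sd(x)))
      model$bn <- bl$fw$bn
      bw <- netBackward(model, bl$fw, bl$dlogits)
      st <- .sgdStep(model$params, bw$grads, vel, train_cfg$lr,
                     train_cfg$momentum)
      model$params <- st$params
      vel <- st$vel
      log <- rbind(log, data.frame(epoch = ep, step = bi,
                                   L_GD = bl$loss$L_GD,
                                   L_CE = bl$loss$L_CE,
                                   L_Overall = bl$loss$L_Overall))
    }
    # validation: region dice over validation slices; the checkpoint is
    # selected by the ET/TC/WT mean so sub-label differentiation counts,
    # not just the whole-tumor extent
    vd <- NA_real_; vmean <- NA_real_
    if (length(va_slices) > 0) {
      preds <- predictSlices(model, va_slices,
                             batch_size = train_cfg$batch_size)
      regs <- list(ET = function(a) a == 3L,
                   TC = function(a) a == 1L | a == 3L,
                   WT = function(a) a != 0L)
      rd <- vapply(regs, function(f) {
        inter <- 0; psum <- 0; tsum <- 0
        for (i in seq_along(va_slices)) {
          pw <- f(preds[[i]]); tw <- f(va_slices[[i]]$label)
          inter <- inter + sum(pw & tw); psum <- psum + sum(pw)
          tsum <- tsum + sum(tw)
        }
        if (psum + tsum == 0) 1 else 2 * inter / (psum + tsum)
      }, 0)
      vd <- rd[["WT"]]
      vmean <- mean(rd)
      if (vmean > best$dice) best <- list(dice = vmean, model = model)
    }
    val_log <- rbind(val_log, data.frame(epoch = ep, val_wt_dice = vd,
                                         val_mean_dice = vmean))
    if (verbose)
      message(sprintf("fold %d epoch %d: loss %.4f, val WT dice %.4f",
                      fold_idx, ep, mean(tail(log$L_Overall, nb)), vd))
  }
  if (is.null(best$model)) best <- list(dice = NA_real_, model = model)
  best_wt <- if (all(is.na(val_log$val_mean_dice))) NA_real_ else
    val_log$val_wt_dice[which.max(val_log$val_mean_dice)]
  list(model = best$model, last_model = model,
       best_val_dice = best_wt, best_val_mean_dice = best$dice,
       log = log, val_log = val_log)
}

#' Predict class-index maps for a list of slices
#'
#' @param model trained model
#' @param slices list of slice pairs
#' @param batch_size forward batch size
#' @return list of 2D integer class-index maps
#' @export
predictSlices <- function(model, slices, batch_size = 16L) {
  out <- vector("list", length(slices))
  i <- 1L
  while (i <= length(slices)) {
    idx <- i:min(i + batch_size - 1L, length(slices))
    d <- dim(slices[[idx[1]]]$image)
    x <- array(0, dim = c(d, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- slices[[idx[j]]]$image
    fw <- netForward(model, x, training = FALSE)
    for (j in seq_along(idx)) {
      pr <- fw$probs[, , , j]
      cls <- apply(pr, c(1, 2), which.max) - 1L
      out[[idx[j]]] <- cls
    }
    i <- i + length(idx)
  }
  out
}

#' Volume-level inference
#'
#' Forward-passes every axial slice of a preprocessed case, stacks the
#' per-slice probabilities, argmax-decodes to BraTS labels and maps the
#' result back to the original case geometry.
#'
#' @param model trained model
#' @param pp output of \code{\link{preprocessCase}} (all slices are used,
#'   regardless of the training filter)
#' @param batch_size forward batch size
#' @param channel_mask optional logical length-4 vector; channels set to
#'   FALSE are replaced by the zero signal at inference (modality
#'   ablation)
#' @return list with \code{labels} (\code{LabelVolume} in original
#'   geometry) and \code{probs} [H, W, Z, C] in cropped space
#' @export
predictVolume <- function(model, pp, batch_size = 16L,
                          channel_mask = NULL) {
  slices <- extractAxialSlices(pp, training_only = FALSE)
  if (!is.null(channel_mask)) {
    stopifnot(length(channel_mask) == 4L)
    for (i in seq_along(slices))
      for (c in which(!channel_mask)) slices[[i]]$image[, , c] <- 0
  }
  nz <- length(slices)
  d <- dim(pp$x)[1:2]
  C <- model$cfg$num_classes
  probs <- array(0, dim = c(d[1], d[2], nz, C))
  cls <- vector("list", nz)
  i <- 1L
  while (i <= nz) {
    idx <- i:min(i + batch_size - 1L, nz)
    x <- array(0, dim = c(d[1], d[2], 4L, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- slices[[idx[j]]]$image
    fw <- netForward(model, x, training = FALSE)
    for (j in seq_along(idx)) {
      pr <- fw$probs[, , , j]
      probs[, , idx[j], ] <- pr
      cls[[idx[j]]] <- apply(pr, c(1, 2), which.max) - 1L
    }
    i <- i + length(idx)
  }
  labels <- reassemblePrediction(cls, seq_len(nz), pp$record)
  list(labels = labels, probs = probs)
}
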