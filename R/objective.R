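#' Generalized dice loss
#'
#' Multi-class dice loss with adaptive per-class weights
#' \eqn{W_c = 1 / (\sum_n y_{nc} + \epsilon_w)^2} countering class
#' imbalance. Class sums are pooled over the whole batch. The loss is
#' \deqn{L_{GD} = 1 - \frac{2 \sum_c W_c \sum_n y_{nc} s_{nc} +
#'   \epsilon}{\sum_c W_c (\sum_n y_{nc} + \sum_n s_{nc}) + \epsilon}.}
#'
#' The weight of a class absent from the batch is set to zero (the
#' limit-consistent guard: an unbounded weight on an empty class would
#' only penalize its predicted volume and destabilizes training).
#'
#' @param s numeric array of softmax predictions, last axis = classes
#' @param y one-hot targets, same shape as \code{s}
#' @param eps smoothing term in numerator and denominator (default 1e-5)
#' @param grad also return the gradient with respect to \code{s}
#' @return list with \code{loss}, per-class weights \code{W}, and
#'   optionally \code{ds}
#' @export
generalizedDiceLoss <- function(s, y, eps = 1e-5, grad = FALSE) {
  stopifnot(identical(dim(s), dim(y)))
  C <- tail(dim(s), 1)
  sm <- matrix(s, ncol = C)
  ym <- matrix(y, ncol = C)
  ysum <- colSums(ym)
  ssum <- colSums(sm)
  inter <- colSums(ym * sm)
  W <- ifelse(ysum > 0, 1 / ysum^2, 0)
  num <- 2 * sum(W * inter) + eps
  den <- sum(W * (ysum + ssum)) + eps
  loss <- 1 - num / den
  out <- list(loss = loss, W = W)
  if (grad) {
    # d num / d s_nc = 2 W_c y_nc ; d den / d s_nc = W_c
    ds <- -(2 * ym %*% diag(W, C, C) * den - num *
              matrix(W, nrow(ym), C, byrow = TRUE)) / den^2
    dim(ds) <- dim(s)
    out$ds <- ds
  }
  out
}

#' Categorical cross-entropy
#'
#' Mean over pixels of \eqn{-\sum_c y_c \log s_c}, with a probability
#' floor inside the log for numerical safety.
#'
#' @inheritParams generalizedDiceLoss
#' @param floor clipping floor for probabilities (default 1e-7)
#' @return list with \code{loss} and optionally \code{ds}
#' @export
categoricalCrossEntropy <- function(s, y, floor = 1e-7, grad = FALSE) {
  stopifnot(identical(dim(s), dim(y)))
  C <- tail(dim(s), 1)
  N <- length(s) / C
  sc <- pmax(s, floor)
  loss <- -sum(y * log(sc)) / N
  out <- list(loss = loss)
  if (grad) {
    ds <- -(y / sc) * (s > floor) / N
    dim(ds) <- dim(s)
    out$ds <- ds
  }
  out
}

#' Combined training objective
#'
#' \eqn{L_{Overall} = L_{GD} + L_{CE}}, the exact sum of the generalized
#' dice and cross-entropy terms; optionally also the gradient with respect
#' to the pre-softmax logits (chained through the softmax).
#'
#' @inheritParams generalizedDiceLoss
#' @param logits optional logits array matching \code{s}; required when
#'   \code{grad = TRUE} to return \code{dlogits}
#' @return list with \code{L_GD}, \code{L_CE}, \code{L_Overall}, \code{W},
#'   and optionally \code{ds} / \code{dlogits}
#' @export
overallLoss <- function(s, y, eps = 1e-5, floor = 1e-7,
                        grad = FALSE, logits = NULL) {
  gd <- generalizedDiceLoss(s, y, eps = eps, grad = grad)
  ce <- categoricalCrossEntropy(s, y, floor = floor, grad = grad)
  out <- list(L_GD = gd$loss, L_CE = ce$loss,
              L_Overall = gd$loss + ce$loss, W = gd$W)
  if (grad) {
    ds <- gd$ds + ce$ds
    out$ds <- ds
    # chain through softmax: dl_k = s_k (g_k - sum_c g_c s_c)
    C <- tail(dim(s), 1)
    sm <- matrix(s, ncol = C)
    gm <- matrix(ds, ncol = C)
    dot <- rowSums(gm * sm)
    dl <- sm * (gm - dot)
    dim(dl) <- dim(s)
    out$dlogits <- dl
  }
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2|P \cap T| / (|P| + |T|)}; two empty masks give 1 by convention.
#'
#' @param pred,truth logical/0-1 arrays of identical shape
#' @return scalar in [0, 1]
#' @export
diceCoefficient <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  p <- sum(pred != 0)
  t <- sum(truth != 0)
  if (p + t == 0) return(1)
  2 * sum(pred != 0 & truth != 0) / (p + t)
}

#' Surface voxels of a binary mask
#'
#' Mask voxels with at least one 6-neighbor outside the mask (volume
#' boundaries count as outside-facing).
#'
#' @param mask logical 3D (or 2D) array
#' @return integer matrix of voxel coordinates (1-based), one row each
#' @export
surfaceVoxels <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  m <- mask != 0
  interior <- array(TRUE, dim = d)
  shift_ok <- function(ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(value = do.call(`[`, c(list(m), idx_src)))))
    out
  }
  for (ax in 1:3) {
    if (d[ax] == 1) { interior[] <- FALSE; break }
    interior <- interior & shift_ok(ax, 1) & shift_ok(ax, -1)
  }
  surf <- m & !interior
  which(surf, arr.ind = TRUE)
}

#' 95th percentile Hausdorff distance between two binary masks
#'
#' Pooled convention: nearest-neighbor distances from every surface voxel
#' of P to the surface of T and vice versa are pooled into one set, whose
#' 95th percentile (linear-interpolation quantile) is returned, scaled by
#' the voxel spacing in mm. With \code{mode = "max_directed"} the BraTS
#' tooling convention (max of the two directed 95th percentiles) is used
#' instead.
#'
#' @param pred,truth binary arrays of identical shape
#' @param spacing voxel spacing in mm
#' @param mode "pooled" (default) or "max_directed"
#' @param empty_sentinel value returned when exactly one mask is empty;
#'   default NULL = the image diagonal in mm. Two empty masks give 0.
#' @return distance in mm
#' @export
hausdorff95 <- function(pred, truth, spacing = c(1, 1, 1),
                        mode = c("pooled", "max_directed"),
                        empty_sentinel = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(pred), dim(truth)))
  d <- dim(pred); if (length(d) == 2) d <- c(d, 1L)
  spacing <- rep_len(spacing, 3)
  pe <- sum(pred != 0) == 0
  te <- sum(truth != 0) == 0
  if (pe && te) return(0)
  if (pe || te) {
    if (is.null(empty_sentinel))
      empty_sentinel <- sqrt(sum((d * spacing)^2))
    return(empty_sentinel)
  }
  A <- surfaceVoxels(pred)
  B <- surfaceVoxels(truth)
  Am <- sweep(A, 2, spacing, `*`)
  Bm <- sweep(B, 2, spacing, `*`)
  dab <- cpp_nn_dists(Am, Bm)
  dba <- cpp_nn_dists(Bm, Am)
  if (mode == "pooled") {
    as.numeric(quantile(c(dab, dba), 0.95))
  } else {
    max(as.numeric(quantile(dab, 0.95)), as.numeric(quantile(dba, 0.95)))
  }
}

#' Region-wise metric report for one case
#'
#' DSC and HD95 for the ET, TC and WT evaluation regions.
#'
#' @param pred,truth \code{LabelVolume}s (or integer arrays over
#'   {0,1,2,4}) of identical geometry
#' @param spacing voxel spacing in mm (taken from \code{pred} if it is a
#'   \code{LabelVolume})
#' @param hd95_mode see \code{\link{hausdorff95}}
#' @return data.frame with columns region, dsc, hd95
#' @export
evaluateRegions <- function(pred, truth, spacing = NULL,
                            hd95_mode = "pooled") {
  if (is(pred, "LabelVolume")) {
    if (is.null(spacing)) spacing <- pred@spacing
    pred <- labelArray(pred)
  }
  if (is(truth, "LabelVolume")) truth <- labelArray(truth)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  rp <- deriveRegions(pred)
  rt <- deriveRegions(truth)
  data.frame(
    region = c("ET", "TC", "WT"),
    dsc = vapply(c("ET", "TC", "WT"),
                 function(r) diceCoefficient(rp[[r]], rt[[r]]), 0),
    hd95 = vapply(c("ET", "TC", "WT"),
                  function(r) hausdorff95(rp[[r]], rt[[r]], spacing,
                                          mode = hd95_mode), 0),
    row.names = NULL)
}
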