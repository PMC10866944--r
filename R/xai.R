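#' Class-score specification for Grad-CAM
#'
#' Defines the scalar \eqn{y^c} whose gradient is taken: the class-c
#' scores (logits, or softmax probabilities) aggregated over all pixels,
#' over the pixels predicted as class c (default; falls back to all pixels
#' when the class is absent from the prediction), or over a caller-given
#' ROI mask.
#'
#' @param target_class class index in 0..3 (0 = background, 1 = necrotic
#'   core, 2 = edema, 3 = enhancing tumor)
#' @param pixels aggregation mode
#' @param source "logit" (default) or "softmax"
#' @param roi logical [H, W] mask, required for \code{pixels = "roi"}
#' @return a \code{classScoreSpec} list
#' @export
classScoreSpec <- function(target_class,
                           pixels = c("predicted", "all", "roi"),
                           source = c("logit", "softmax"), roi = NULL) {
  pixels <- match.arg(pixels)
  source <- match.arg(source)
  if (pixels == "roi" && is.null(roi)) stop("roi mode requires a mask")
  stopifnot(target_class %in% 0:3)
  structure(list(target_class = as.integer(target_class), pixels = pixels,
                 source = source, roi = roi),
            class = "classScoreSpec")
}

.scoreGradient <- function(fw, spec) {
  # gradient of y^c with respect to the logits, [H, W, C, 1]
  d <- dim(fw$logits)
  c1 <- spec$target_class + 1L
  sel <- switch(spec$pixels,
    all = matrix(TRUE, d[1], d[2]),
    predicted = {
      pred <- apply(fw$probs[, , , 1], c(1, 2), which.max)
      m <- pred == c1
      if (!any(m)) m[] <- TRUE    # fallback: class absent
      m
    },
    roi = spec$roi)
  g <- array(0, dim = d)
  if (spec$source == "logit") {
    gc <- array(0, dim = d[1:2]); gc[sel] <- 1
    g[, , c1, 1] <- gc
  } else {
    # y = sum over selected pixels of softmax_c; chain through softmax
    p <- fw$probs[, , , 1]
    pc <- p[, , c1]
    for (k in seq_len(d[3])) {
      gk <- pc * ((k == c1) - p[, , k])
      gk[!sel] <- 0
      g[, , k, 1] <- gk
    }
  }
  g
}

.bilinearResize <- function(m, out_dim) {
  hi <- nrow(m); wi <- ncol(m)
  ho <- out_dim[1]; wo <- out_dim[2]
  if (hi == ho && wi == wo) return(m)
  sy <- hi / ho; sx <- wi / wo
  yi <- pmin(pmax((seq_len(ho) - 0.5) * sy + 0.5, 1), hi)
  xi <- pmin(pmax((seq_len(wo) - 0.5) * sx + 0.5, 1), wi)
  y0 <- pmin(floor(yi), hi - 1); x0 <- pmin(floor(xi), wi - 1)
  if (hi == 1) y0 <- rep(1, ho)
  if (wi == 1) x0 <- rep(1, wo)
  fy <- yi - y0; fx <- xi - x0
  y1 <- pmin(y0 + 1, hi); x1 <- pmin(x0 + 1, wi)
  m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
}

#' Grad-CAM saliency map for a tagged layer
#'
#' Computes \eqn{\alpha_k = \frac{1}{N}\sum_{x,y} \partial y^c /
#' \partial A^k_{x,y}} (N = pixel count of the layer's grid) and the
#' heatmap \eqn{ReLU(\sum_k \alpha_k A^k)}, bilinearly upsampled to the
#' input size and min-max normalized to [0, 1]. Explanation generation is
#' post hoc: model weights are never modified.
#'
#' @param model trained model
#' @param image one slice image [H, W, 4]
#' @param layer a layer tag (see \code{model$tags}); e.g. "EB1".."EB4",
#'   "BOT", "DB1".."DB4", "OUT"
#' @param spec a \code{\link{classScoreSpec}}
#' @return list with \code{heatmap} [H, W] in [0, 1], \code{alpha},
#'   \code{raw} (pre-normalization map at native resolution),
#'   \code{all_zero} flag, \code{layer} and \code{spec}
#' @export
gradCAM <- function(model, image, layer, spec) {
  if (!layer %in% model$tags)
    stop(sprintf("unknown layer tag '%s'; available: %s", layer,
                 paste(model$tags, collapse = ", ")))
  d <- dim(image)
  x <- array(image, dim = c(d[1], d[2], d[3], 1L))
  fw <- netForward(model, x, training = FALSE, keep_cache = TRUE)
  dlogits <- .scoreGradient(fw, spec)
  bw <- netBackward(model, fw, dlogits, want_tags = layer)
  A <- fw$acts[[layer]][, , , 1, drop = TRUE]
  G <- bw$tag_grads[[layer]][, , , 1, drop = TRUE]
  if (length(dim(A)) == 2) dim(A) <- c(dim(A), 1L)
  if (length(dim(G)) == 2) dim(G) <- c(dim(G), 1L)
  nk <- dim(A)[3]
  alpha <- vapply(seq_len(nk), function(k) mean(G[, , k]), 0)
  raw <- array(0, dim = dim(A)[1:2])
  for (k in seq_len(nk)) raw <- raw + alpha[k] * A[, , k]
  raw <- pmax(raw, 0)
  up <- .bilinearResize(raw, d[1:2])
  all_zero <- max(up) <= 0
  heat <- if (all_zero) up else (up - min(up)) / (max(up) - min(up))
  list(heatmap = heat, alpha = alpha, raw = raw, all_zero = all_zero,
       layer = layer, spec = spec)
}

#' Saliency maps across a set of layers
#'
#' @param model trained model
#' @param image slice image [H, W, 4]
#' @param layers character vector of tags; default: every tagged layer
#' @param spec a \code{\link{classScoreSpec}}
#' @return named list of \code{\link{gradCAM}} results
#' @export
layerSweep <- function(model, image, layers = model$tags, spec) {
  bad <- setdiff(layers, model$tags)
  if (length(bad))
    stop(sprintf("unknown layer tags: %s", paste(bad, collapse = ", ")))
  out <- lapply(layers, function(l) gradCAM(model, image, l, spec))
  names(out) <- layers
  out
}

#' Modality-ablation attribution experiment
#'
#' Re-runs volume inference with channels zeroed at inference time (the
#' background value after z-scoring): for every modality m, once keeping
#' only m ("keep-only") and once zeroing only m ("leave-one-out").
#' Region dice against the ground truth is recorded for each condition,
#' plus output-layer Grad-CAM maps per tumor class on the central tumor
#' slice for the keep-only conditions.
#'
#' @param model trained model
#' @param pp preprocessed case (\code{\link{preprocessCase}}), with labels
#' @param truth ground-truth \code{LabelVolume} in original geometry
#' @param with_saliency also compute per-class Grad-CAM maps
#' @return list with \code{report} (data.frame: condition, modality,
#'   dsc_ET, dsc_TC, dsc_WT) and \code{saliency}
#' @export
modalityAblation <- function(model, pp, truth, with_saliency = FALSE) {
  conds <- rbind(
    data.frame(condition = "keep_only", modality = MODALITIES),
    data.frame(condition = "leave_one_out", modality = MODALITIES))
  rows <- list()
  saliency <- list()
  truth_arr <- labelArray(truth)
  for (i in seq_len(nrow(conds))) {
    m <- conds$modality[i]
    mask <- if (conds$condition[i] == "keep_only") MODALITIES == m
            else MODALITIES != m
    pv <- predictVolume(model, pp, channel_mask = mask)
    ev <- evaluateRegions(labelArray(pv$labels), truth_arr,
                          spacing = truth@spacing)
    rows[[i]] <- data.frame(condition = conds$condition[i], modality = m,
                            dsc_ET = ev$dsc[ev$region == "ET"],
                            dsc_TC = ev$dsc[ev$region == "TC"],
                            dsc_WT = ev$dsc[ev$region == "WT"])
  }
  if (with_saliency) {
    # central tumor slice in cropped space
    yz <- apply(pp$y != 0, 3, sum)
    z <- which.max(yz)
    img <- pp$x[, , z, , drop = TRUE]
    dim(img) <- c(dim(pp$x)[1:2], 4L)
    for (cls in 1:3) {
      saliency[[as.character(cls)]] <-
        gradCAM(model, img, "OUT", classScoreSpec(cls))
    }
  }
  list(report = do.call(rbind, rows), saliency = saliency)
}

#' Write a saliency heatmap as NIfTI aligned to the input slice grid
#'
#' @param cam a \code{\link{gradCAM}} result
#' @param path output path
#' @export
saveSaliency <- function(cam, path) {
  img <- RNifti::asNifti(array(cam$heatmap, dim = c(dim(cam$heatmap), 1L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
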