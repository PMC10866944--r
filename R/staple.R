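#' Binary STAPLE expectation-maximization fusion
#'
#' Simultaneous truth and performance level estimation: given K binary
#' segmentations of the same volume, EM alternates between (E-step) the
#' posterior probability that each voxel belongs to the true segmentation
#' given current rater sensitivities p and specificities q, and (M-step)
#' re-estimating p and q from the posteriors, until
#' \eqn{\sum_k |\Delta p_k| + |\Delta q_k| < tol} or \code{max_iter}.
#'
#' @param masks list of K binary arrays (identical shape), or a matrix
#'   with one column per rater
#' @param prior scalar prior probability of foreground; default: the mean
#'   rater-positive fraction
#' @param p_init,q_init initial sensitivities/specificities
#' @param tol convergence tolerance on the performance parameters
#' @param max_iter iteration cap
#' @return list with \code{posterior} (array in [0,1]), \code{p},
#'   \code{q}, \code{iterations}, \code{converged}, and
#'   \code{log_likelihood} trace (observed-data, non-decreasing)
#' @export
stapleBinary <- function(masks, prior = NULL, p_init = 0.99999,
                         q_init = 0.99999, tol = 1e-7, max_iter = 100L) {
  if (is.list(masks)) {
    dm <- dim(masks[[1]])
    D <- vapply(masks, function(m) as.numeric(m != 0), numeric(length(masks[[1]])))
  } else {
    dm <- NULL
    D <- masks != 0
    storage.mode(D) <- "numeric"
  }
  K <- ncol(D)
  stopifnot(K >= 2)
  if (is.null(prior)) prior <- mean(D)
  stopifnot(prior >= 0, prior <= 1)
  p <- rep(p_init, K)
  q <- rep(q_init, K)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  Wv <- NULL
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    # E-step
    la <- log(prior + eps) +
      D %*% log(p + eps) + (1 - D) %*% log(1 - p + eps)
    lb <- log(1 - prior + eps) +
      (1 - D) %*% log(q + eps) + D %*% log(1 - q + eps)
    m <- pmax(la, lb)
    a <- exp(la - m); b <- exp(lb - m)
    Wv <- as.vector(a / (a + b))
    ll <- c(ll, sum(m + log(a + b)))
    # M-step
    sw <- sum(Wv); swc <- sum(1 - Wv)
    p_new <- if (sw > 0) as.vector(crossprod(D, Wv)) / sw else p
    q_new <- if (swc > 0) as.vector(crossprod(1 - D, 1 - Wv)) / swc else q
    delta <- sum(abs(p_new - p)) + sum(abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("STAPLE did not converge within %d iterations", max_iter))
  post <- Wv
  if (!is.null(dm)) dim(post) <- dm
  list(posterior = post, p = p, q = q, iterations = it,
       converged = converged, log_likelihood = ll)
}

#' Multi-label STAPLE fusion of fold predictions
#'
#' Two fusion modes over the bounding box of the union of rater-positive
#' voxels (outside it the fused label is 0):
#'
#' \describe{
#'   \item{"regions" (default)}{hierarchical fusion of the nested
#'     evaluation regions: binary STAPLE is run for WT (any tumor), TC
#'     (labels 1, 4) and ET (label 4); posteriors are thresholded at 0.5,
#'     nesting is enforced by intersection, and labels are reconstructed
#'     (ET -> 4, TC\\ET -> 1, WT\\TC -> 2). Robust for small rater
#'     counts: raters that agree a voxel is tumor but disagree on the
#'     sub-label still keep it inside the fused whole tumor.}
#'   \item{"labels"}{one-vs-rest binary STAPLE per tumor label; each
#'     voxel takes the label with the highest posterior provided it
#'     exceeds the background posterior, ties broken by the fixed
#'     priority 4 > 1 > 2.}
#' }
#'
#' @param stack list of \code{LabelVolume}s (or integer arrays) with
#'   identical geometry, one per rater/fold model
#' @param labels tumor labels to fuse (labels mode)
#' @param tol,max_iter passed to \code{\link{stapleBinary}}
#' @param mode fusion mode, see above
#' @return fused \code{LabelVolume} (or integer array if the inputs were
#'   arrays)
#' @export
stapleMultilabel <- function(stack, labels = c(1L, 2L, 4L), tol = 1e-7,
                             max_iter = 100L,
                             mode = c("regions", "labels")) {
  mode <- match.arg(mode)
  asS4 <- is(stack[[1]], "LabelVolume")
  arrs <- lapply(stack, function(s)
    if (is(s, "LabelVolume")) labelArray(s) else s)
  d <- dim(arrs[[1]])
  stopifnot(all(vapply(arrs, function(a) identical(dim(a), d), TRUE)))
  union_pos <- Reduce(`|`, lapply(arrs, function(a) a != 0L))
  fused <- array(0L, dim = d)
  if (any(union_pos)) {
    idx <- which(union_pos, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 1L, 1L)
    hi <- pmin(apply(idx, 2, max) + 1L, d)
    sub <- lapply(arrs, function(a)
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
    fusePosterior <- function(masks) {
      if (!any(vapply(masks, any, TRUE)))
        return(array(0, dim = dim(sub[[1]])))
      stapleBinary(masks, tol = tol, max_iter = max_iter)$posterior
    }
    if (mode == "regions") {
      wt <- fusePosterior(lapply(sub, function(a) a != 0L)) > 0.5
      tc <- fusePosterior(lapply(sub, function(a) a == 1L | a == 4L)) > 0.5 & wt
      et <- fusePosterior(lapply(sub, function(a) a == 4L)) > 0.5 & tc
      bestlab <- array(0L, dim = dim(sub[[1]]))
      bestlab[wt & !tc] <- 2L
      bestlab[tc & !et] <- 1L
      bestlab[et] <- 4L
    } else {
      post <- lapply(labels, function(lb)
        fusePosterior(lapply(sub, function(a) a == lb)))
      names(post) <- as.character(labels)
      # tie-break priority 4 > 1 > 2: evaluate in order, strict improvement
      prio <- intersect(c(4L, 1L, 2L), labels)
      best <- array(0, dim = dim(sub[[1]]))
      bestlab <- array(0L, dim = dim(sub[[1]]))
      for (lb in prio) {
        pl <- post[[as.character(lb)]]
        take <- pl > best
        bestlab[take] <- lb
        best[take] <- pl[take]
      }
      bestlab[best <= 1 - best] <- 0L   # must beat the background posterior
    }
    fused[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- bestlab
  }
  if (asS4) {
    tmpl <- stack[[1]]
    LabelVolume(fused, spacing = tmpl@spacing, affine = tmpl@affine,
                orientation = tmpl@orientation)
  } else fused
}
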