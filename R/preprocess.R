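#' Compute the brain mask of a multimodal volume
#'
#' Union of nonzero voxels across the four channels, with connected
#' components (6-connectivity) smaller than \code{min_component_frac} of
#' the largest component removed. Inputs are assumed skull-stripped with
#' background already at 0; the component filter makes the mask robust to
#' isolated nonzero speckles.
#'
#' @param vol a \code{MultimodalVolume}
#' @param min_component_frac components smaller than this fraction of the
#'   largest are dropped (default 0.01)
#' @return 3D logical array
#' @export
brainMask <- function(vol, min_component_frac = 0.01) {
  stk <- channelStack(vol)
  m <- apply(stk != 0, c(1, 2, 3), any)
  if (!any(m)) stop("volume is entirely zero: no brain voxels")
  cc <- cpp_label_components(as.logical(m), dim(m))
  sizes <- cc$sizes
  keep <- which(sizes >= min_component_frac * max(sizes))
  out <- array(cc$labels %in% keep & cc$labels > 0L, dim = dim(m))
  out
}

#' Zero all non-brain voxels
#'
#' Idempotent: voxels outside the brain mask are set to exactly 0 in all
#' channels; voxels inside are untouched.
#'
#' @inheritParams brainMask
#' @return list with \code{volume} (masked \code{MultimodalVolume}) and
#'   \code{mask} (logical array)
#' @export
zeroNonbrain <- function(vol, min_component_frac = 0.01) {
  m <- brainMask(vol, min_component_frac)
  ch <- vol@channels
  for (i in seq_along(ch)) ch[[i]][!m] <- 0
  out <- MultimodalVolume(ch, spacing = vol@spacing, affine = vol@affine,
                          orientation = vol@orientation)
  list(volume = out, mask = m)
}

#' Per-volume, per-channel z-score normalization over brain voxels
#'
#' Each channel is standardized using the mean and population standard
#' deviation of its brain voxels only; non-brain voxels stay exactly 0.
#' A constant channel (zero standard deviation) falls back to std = 1 and
#' sets a flag in the returned record.
#'
#' @param vol a \code{MultimodalVolume} (background already zeroed)
#' @param mask 3D logical brain mask
#' @return list with \code{volume} and \code{norm} (per-channel
#'   \code{mean}, \code{sd}, \code{fallback})
#' @export
zscoreNormalize <- function(vol, mask) {
  stopifnot(any(mask))
  ch <- vol@channels
  norm <- list()
  for (m in MODALITIES) {
    v <- ch[[m]][mask]
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))  # population convention
    fb <- FALSE
    if (sdev == 0) { sdev <- 1; fb <- TRUE }
    x <- ch[[m]]
    x[mask] <- (x[mask] - mu) / sdev
    x[!mask] <- 0
    ch[[m]] <- x
    norm[[m]] <- list(mean = mu, sd = sdev, fallback = fb)
  }
  vol2 <- MultimodalVolume(ch, spacing = vol@spacing, affine = vol@affine,
                           orientation = vol@orientation)
  list(volume = vol2, norm = norm)
}

.cropAxis <- function(n, s) as.integer(floor((n - s) / 2))

.cropPad1 <- function(x, off, s, axis) {
  # crop (off >= 0) or zero-pad (off < 0) axis `axis` of array x to length s
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  if (off >= 0) {
    idx[[axis]] <- (off + 1):(off + s)
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  } else {
    dn <- d; dn[axis] <- s
    out <- array(if (is.integer(x)) 0L else 0, dim = dn)
    idx[[axis]] <- (-off + 1):(-off + d[axis])
    out <- do.call(`[<-`, c(list(out), idx, list(value = x)))
    out
  }
}

#' Center-crop (or pad) the in-plane axes of a case
#'
#' Crops the geometric center of the first two array axes to
#' \code{size}; inputs smaller than \code{size} are zero-padded first.
#' The third (axial) axis is untouched. Offsets (negative = padding) and
#' the original shape are recorded so predictions can be mapped back.
#'
#' @param x array with in-plane axes first (e.g. [H, W, Z, C] or [H, W, Z])
#' @param size in-plane target, default c(192, 192)
#' @return list with \code{x} (cropped array) and \code{record}
#'   (\code{crop_offsets}, \code{original_shape}, \code{crop_size})
#' @export
centerCrop <- function(x, size = c(192L, 192L)) {
  d <- dim(x)
  off <- c(.cropAxis(d[1], size[1]), .cropAxis(d[2], size[2]))
  out <- .cropPad1(x, off[1], size[1], 1L)
  out <- .cropPad1(out, off[2], size[2], 2L)
  list(x = out,
       record = list(crop_offsets = off, original_shape = d[1:2],
                     crop_size = as.integer(size)))
}

#' Undo a center crop
#'
#' Places a cropped array back into the original in-plane geometry;
#' regions lost to padding are discarded, regions outside the crop are
#' filled with \code{fill}.
#'
#' @param x cropped array (in-plane axes first)
#' @param record the \code{record} returned by \code{\link{centerCrop}}
#' @param fill value for voxels outside the crop window (default 0)
#' @return array with the original in-plane shape
#' @export
invertCrop <- function(x, record, fill = 0L) {
  off <- record$crop_offsets
  orig <- record$original_shape
  s <- record$crop_size
  d <- dim(x)
  dn <- d; dn[1:2] <- orig
  out <- array(if (is.integer(x)) as.integer(fill) else fill, dim = dn)
  # source window inside the cropped array, destination window in out
  src1 <- if (off[1] >= 0) 1:s[1] else (-off[1] + 1):(-off[1] + orig[1])
  dst1 <- if (off[1] >= 0) (off[1] + 1):(off[1] + s[1]) else 1:orig[1]
  src2 <- if (off[2] >= 0) 1:s[2] else (-off[2] + 1):(-off[2] + orig[2])
  dst2 <- if (off[2] >= 0) (off[2] + 1):(off[2] + s[2]) else 1:orig[2]
  idxs <- rep(list(quote(expr = )), length(d)); idxs[[1]] <- src1; idxs[[2]] <- src2
  idxd <- rep(list(quote(expr = )), length(d)); idxd[[1]] <- dst1; idxd[[2]] <- dst2
  piece <- do.call(`[`, c(list(x), idxs, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idxd, list(value = piece)))
  out
}

#' Preprocess one case for the network
#'
#' Runs the full chain: brain-FOV zeroing, per-volume z-score over brain
#' voxels, center crop/pad of the in-plane axes, and axial slice
#' extraction, recording everything needed to reassemble predictions in
#' the original geometry.
#'
#' @param case a list as returned by \code{\link{loadCase}}, or a
#'   \code{MultimodalVolume} (then \code{labels} may be given separately)
#' @param labels optional \code{LabelVolume}
#' @param crop_size in-plane size fed to the network
#' @param min_brain_fraction slices with a smaller fraction of brain
#'   pixels are excluded from training (all slices are kept for
#'   inference); default 0.01
#' @return list with \code{x} [H, W, Z, 4] normalized image stack,
#'   \code{y} [H, W, Z] class-index array or NULL, \code{mask} cropped
#'   brain mask, \code{record} (crop + normalization + geometry) and
#'   \code{keep} logical vector of training-eligible slices
#' @export
preprocessCase <- function(case, labels = NULL, crop_size = c(192L, 192L),
                           min_brain_fraction = 0.01) {
  if (is.list(case) && !is(case, "MultimodalVolume")) {
    labels <- case$labels
    vol <- case$volume
  } else vol <- case
  zb <- zeroNonbrain(vol)
  zs <- zscoreNormalize(zb$volume, zb$mask)
  stk <- channelStack(zs$volume)
  cr <- centerCrop(stk, crop_size)
  mk <- centerCrop(array(as.integer(zb$mask), dim = dim(zb$mask)), crop_size)
  y <- NULL
  if (!is.null(labels)) {
    lc <- centerCrop(labelArray(labels), crop_size)
    y <- labelsToClassIndices(lc$x)
  }
  maskc <- mk$x == 1L
  bf <- apply(maskc, 3, mean)
  rec <- c(cr$record,
           list(norm = zs$norm, spacing = vol@spacing, affine = vol@affine,
                orientation = vol@orientation,
                n_slices = dim(stk)[3]))
  list(x = cr$x, y = y, mask = maskc, record = rec,
       keep = bf >= min_brain_fraction)
}

#' Extract axial slice pairs from a preprocessed case
#'
#' @param pp output of \code{\link{preprocessCase}}
#' @param training_only keep only slices with enough brain content
#' @return list of slice pairs: \code{image} [H, W, 4], \code{label}
#'   [H, W] class indices (or NULL), \code{index} axial position
#' @export
extractAxialSlices <- function(pp, training_only = FALSE) {
  z_idx <- seq_len(dim(pp$x)[3])
  if (training_only) z_idx <- z_idx[pp$keep]
  lapply(z_idx, function(z) {
    img <- pp$x[, , z, , drop = FALSE]
    dim(img) <- c(dim(pp$x)[1:2], 4L)
    lab <- NULL
    if (!is.null(pp$y)) {
      lab <- pp$y[, , z]
      dim(lab) <- dim(pp$x)[1:2]
    }
    list(image = img, label = lab, index = z)
  })
}

#' Reassemble per-slice predictions into a volume in original geometry
#'
#' @param slices list of 2D integer class-index maps
#' @param indices axial index of each slice
#' @param record preprocess record of the case
#' @return \code{LabelVolume} in the original case geometry with BraTS
#'   labels
#' @export
reassemblePrediction <- function(slices, indices, record) {
  s <- record$crop_size
  vol <- array(0L, dim = c(s[1], s[2], record$n_slices))
  for (i in seq_along(slices)) vol[, , indices[i]] <- slices[[i]]
  full <- invertCrop(vol, record, fill = 0L)
  LabelVolume(indicesToLabels(full), spacing = record$spacing,
              affine = record$affine, orientation = record$orientation)
}
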