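#' On-the-fly augmentation configuration
#'
#' Spatial transforms (shift, flip, rotation, zoom) are applied jointly to
#' image and label; intensity transforms (brightness scale, Gaussian
#' noise) to the image channels only. Ranges follow the training recipe:
#' rotation magnitude up to 20 degrees (random sign), zoom within +/-20%,
#' brightness scale within +/-20%, additive Gaussian noise with standard
#' deviation 0.01 in normalized intensity units. The shift range has no
#' published value; the default is 10% of the image size.
#'
#' @param shift_fraction max in-plane translation, fraction of size
#' @param flip_prob probability of a flip per in-plane axis
#' @param rotation_max_deg max rotation magnitude in degrees
#' @param zoom_max_fraction max relative zoom deviation
#' @param brightness_max_fraction max relative brightness deviation
#' @param noise_std Gaussian noise sd (normalized units)
#' @return an \code{augmentConfig} list
#' @export
augmentConfig <- function(shift_fraction = 0.1, flip_prob = 0.5,
                          rotation_max_deg = 20, zoom_max_fraction = 0.2,
                          brightness_max_fraction = 0.2,
                          noise_std = 0.01) {
  stopifnot(shift_fraction >= 0, shift_fraction <= 1,
            flip_prob >= 0, flip_prob <= 1, rotation_max_deg >= 0,
            zoom_max_fraction >= 0, zoom_max_fraction <= 1,
            brightness_max_fraction >= 0, noise_std >= 0)
  structure(list(shift_fraction = shift_fraction, flip_prob = flip_prob,
                 rotation_max_deg = rotation_max_deg,
                 zoom_max_fraction = zoom_max_fraction,
                 brightness_max_fraction = brightness_max_fraction,
                 noise_std = noise_std),
            class = "augmentConfig")
}

#' Sample one set of augmentation parameters
#'
#' Draws: per-axis shift ~ U(-s, s) pixels, per-axis flips ~
#' Bernoulli(flip_prob), rotation angle ~ U(0, max) degrees with random
#' sign, zoom ~ U(1 - z, 1 + z), brightness scale ~ U(1 - b, 1 + b), and
#' a per-pixel, per-channel Gaussian noise field.
#'
#' @param cfg an \code{\link{augmentConfig}}
#' @param size in-plane image size c(H, W)
#' @param n_channels number of image channels (for the noise field)
#' @return list of sampled parameters
#' @export
sampleAugmentParams <- function(cfg, size, n_channels = 4L) {
  s <- cfg$shift_fraction * size
  angle <- runif(1, 0, cfg$rotation_max_deg) * sample(c(-1, 1), 1)
  list(shift = c(runif(1, -s[1], s[1]), runif(1, -s[2], s[2])),
       flip = runif(2) < cfg$flip_prob,
       angle_deg = angle,
       zoom = runif(1, 1 - cfg$zoom_max_fraction, 1 + cfg$zoom_max_fraction),
       brightness = runif(1, 1 - cfg$brightness_max_fraction,
                          1 + cfg$brightness_max_fraction),
       noise = if (cfg$noise_std > 0)
         array(rnorm(prod(size) * n_channels, 0, cfg$noise_std),
               dim = c(size, n_channels)) else NULL)
}

# Affine resampling around the image center: for each output pixel the
# source coordinate under the inverse transform is gathered bilinearly
# (images) or by nearest neighbor (labels); out-of-frame samples get 0.
.affineWarp <- function(img, angle_deg, zoom, shift, flip, nearest = FALSE) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  th <- angle_deg * pi / 180
  gi <- rep(seq_len(H), times = W) - ctr[1]
  gj <- rep(seq_len(W), each = H) - ctr[2]
  # inverse map: undo shift, then rotation/zoom, then flips
  gi2 <- gi - shift[1]
  gj2 <- gj - shift[2]
  si <- (cos(th) * gi2 + sin(th) * gj2) / zoom
  sj <- (-sin(th) * gi2 + cos(th) * gj2) / zoom
  if (flip[1]) si <- -si
  if (flip[2]) sj <- -sj
  si <- si + ctr[1]
  sj <- sj + ctr[2]
  nch <- if (length(d) == 3) d[3] else 1L
  x <- img
  dim(x) <- c(H * W, nch)
  out <- matrix(if (nearest) 0L else 0, H * W, nch)
  if (nearest) {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out[ok, ] <- x[ri[ok] + (rj[ok] - 1) * H, , drop = FALSE]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    gather <- function(ii, jj) {
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      g <- matrix(0, H * W, nch)
      g[ok, ] <- x[ii[ok] + (jj[ok] - 1) * H, , drop = FALSE]
      g
    }
    out <- gather(i0, j0) * ((1 - fi) * (1 - fj)) +
           gather(i0 + 1, j0) * (fi * (1 - fj)) +
           gather(i0, j0 + 1) * ((1 - fi) * fj) +
           gather(i0 + 1, j0 + 1) * (fi * fj)
  }
  dim(out) <- d
  if (nearest) storage.mode(out) <- "integer"
  out
}

#' Apply sampled augmentation parameters to a slice pair
#'
#' Geometry is applied identically to image (bilinear) and label (nearest
#' neighbor); brightness and noise touch the image only. Out-of-frame
#' regions are filled with the background value 0. The label value set can
#' shrink but never grow.
#'
#' @param pair list with \code{image} [H, W, C] and \code{label} [H, W]
#'   (label may be NULL)
#' @param par parameters from \code{\link{sampleAugmentParams}}
#' @return augmented pair
#' @export
applyAugment <- function(pair, par) {
  img <- .affineWarp(pair$image, par$angle_deg, par$zoom, par$shift,
                     par$flip, nearest = FALSE)
  img <- img * par$brightness
  if (!is.null(par$noise)) img <- img + par$noise
  lab <- pair$label
  if (!is.null(lab)) {
    lab <- .affineWarp(lab, par$angle_deg, par$zoom, par$shift, par$flip,
                       nearest = TRUE)
  }
  list(image = img, label = lab, index = pair$index)
}

#' Sample parameters and augment a slice pair in one step
#'
#' @param pair slice pair
#' @param cfg an \code{\link{augmentConfig}}
#' @param seed optional seed making the draw reproducible
#' @return list with the augmented \code{pair} and the sampled
#'   \code{params}
#' @export
augmentPair <- function(pair, cfg, seed = NULL) {
  draw <- function() sampleAugmentParams(cfg, dim(pair$image)[1:2],
                                         dim(pair$image)[3])
  par <- if (is.null(seed)) draw() else withSeed(seed, draw())
  list(pair = applyAugment(pair, par), params = par)
}
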