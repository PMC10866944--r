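#' Default tissue contrast table for phantom cases
#'
#' Mean intensity (arbitrary units) per modality and tissue, encoding the
#' radiological signs the pipeline is expected to exploit: edema bright on
#' FLAIR/T2, enhancing rim bright on T1Gd, necrotic core dark on T1Gd,
#' background exactly 0. Edema is deliberately identical to white matter
#' on T1 and T1Gd, so edema is distinguishable only via the T2/FLAIR
#' channels -- the planted ground truth for modality-attribution tests.
#'
#' @return 4 x 6 numeric matrix, rows = modalities, columns = tissues
#' @export
defaultContrastTable <- function() {
  tbl <- rbind(
    T1    = c(background = 0, white_matter = 0.60, gray_matter = 0.45,
              edema = 0.60, necrotic_core = 0.30, enhancing = 0.50),
    T1Gd  = c(0, 0.60, 0.45, 0.60, 0.15, 0.95),
    T2    = c(0, 0.40, 0.50, 0.80, 0.70, 0.55),
    FLAIR = c(0, 0.40, 0.50, 0.90, 0.55, 0.60))
  colnames(tbl) <- c("background", "white_matter", "gray_matter", "edema",
                     "necrotic_core", "enhancing")
  tbl
}

#' Specification of a synthetic multimodal phantom case
#'
#' The phantom is an ellipsoidal "brain" (outer shell gray matter, interior
#' white matter) containing a nested spherical tumor: necrotic core
#' (label 1) of radius \code{r_core}, enhancing rim (label 4) between
#' \code{r_core} and \code{r_tc}, peritumoral edema (label 2) between
#' \code{r_tc} and \code{r_wt}. Intensities are tissue means from the
#' contrast table plus seeded Gaussian noise; non-brain voxels are exactly
#' 0.
#'
#' @param image_shape voxel grid, default 96 x 96 x 32
#' @param brain_axes ellipsoid semi-axes in voxels
#' @param gm_frac inner boundary of the gray-matter shell, as a fraction of
#'   the brain ellipsoid
#' @param tumor_center tumor center in voxel coordinates
#' @param r_core,r_tc,r_wt nested radii (voxels): necrotic core, tumor
#'   core, whole tumor; must satisfy r_core < r_tc < r_wt
#' @param contrast_table modality x tissue mean intensities
#' @param noise_std Gaussian noise standard deviation (intensity units)
#' @param spacing voxel spacing in mm
#' @param seed integer RNG seed
#' @return a \code{phantomSpec} list
#' @export
phantomSpec <- function(image_shape = c(96L, 96L, 32L),
                        brain_axes = c(38, 38, 14),
                        gm_frac = 0.8,
                        tumor_center = c(58, 42, 16.5),
                        r_core = 4, r_tc = 7, r_wt = 10,
                        contrast_table = defaultContrastTable(),
                        noise_std = 0.04,
                        spacing = c(1, 1, 1),
                        seed = 1L) {
  stopifnot(r_core < r_tc, r_tc < r_wt,
            identical(rownames(contrast_table), MODALITIES),
            all(c("background", "white_matter", "gray_matter", "edema",
                  "necrotic_core", "enhancing") %in%
                colnames(contrast_table)),
            all(contrast_table[, "background"] == 0),
            noise_std >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 brain_axes = brain_axes, gm_frac = gm_frac,
                 tumor_center = tumor_center, r_core = r_core,
                 r_tc = r_tc, r_wt = r_wt,
                 contrast_table = contrast_table,
                 noise_std = noise_std, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

.phantomTissueMap <- function(spec) {
  d <- spec$image_shape
  ctr <- (d + 1) / 2
  ax <- matrix(0, prod(d), 3)
  ax[, 1] <- rep.int(seq_len(d[1]), times = d[2] * d[3])
  ax[, 2] <- rep.int(rep(seq_len(d[2]), each = d[1]), times = d[3])
  ax[, 3] <- rep(seq_len(d[3]), each = d[1] * d[2])
  u <- ((ax[, 1] - ctr[1]) / spec$brain_axes[1])^2 +
       ((ax[, 2] - ctr[2]) / spec$brain_axes[2])^2 +
       ((ax[, 3] - ctr[3]) / spec$brain_axes[3])^2
  r <- sqrt((ax[, 1] - spec$tumor_center[1])^2 +
            (ax[, 2] - spec$tumor_center[2])^2 +
            (ax[, 3] - spec$tumor_center[3])^2)
  tissue <- rep("background", prod(d))
  tissue[u <= 1] <- "gray_matter"
  tissue[u <= spec$gm_frac^2] <- "white_matter"
  intum <- r <= spec$r_wt
  if (any(intum & u > 1))
    stop("tumor radii exceed the brain ellipsoid")
  tissue[intum & r > spec$r_tc] <- "edema"
  tissue[r <= spec$r_tc & r > spec$r_core] <- "enhancing"
  tissue[r <= spec$r_core] <- "necrotic_core"
  array(tissue, dim = d)
}

#' Generate one phantom case
#'
#' Deterministic in \code{spec$seed}: regenerating with the same spec gives
#' bit-identical arrays.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @return list with \code{volume} (\code{MultimodalVolume}),
#'   \code{labels} (\code{LabelVolume}) and \code{tissue} (tissue-name
#'   array)
#' @export
generatePhantomCase <- function(spec) {
  tissue <- .phantomTissueMap(spec)
  d <- spec$image_shape
  lab <- array(0L, dim = d)
  lab[tissue == "necrotic_core"] <- 1L
  lab[tissue == "edema"] <- 2L
  lab[tissue == "enhancing"] <- 4L
  brain <- tissue != "background"
  chans <- withSeed(spec$seed, {
    out <- list()
    for (m in MODALITIES) {
      base <- spec$contrast_table[m, ][tissue]
      dim(base) <- d
      if (spec$noise_std > 0) {
        nz <- array(rnorm(prod(d), 0, spec$noise_std), dim = d)
        base <- base + nz
      }
      base[!brain] <- 0
      out[[m]] <- base
    }
    out
  })
  list(volume = MultimodalVolume(chans, spacing = spec$spacing),
       labels = LabelVolume(lab, spacing = spec$spacing),
       tissue = tissue)
}

#' Generate a cohort of phantom cases in BraTS directory layout
#'
#' Writes \code{n} case directories (\code{case_001}, ...) each holding
#' the four modality files and the ground-truth segmentation as NIfTI,
#' loadable by \code{\link{loadCase}}. Tumor center and radii are jittered
#' deterministically from \code{seed}.
#'
#' @param n number of cases
#' @param out_dir output directory (created if needed)
#' @param base_spec spec shared by all cases
#' @param jitter max absolute voxel jitter of tumor center and radii
#' @param seed cohort seed
#' @return character vector of case directories
#' @export
generatePhantomCohort <- function(n, out_dir, base_spec = phantomSpec(),
                                  jitter = 3, seed = 1L) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(n)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, 101L, i)
    spec_i <- base_spec
    if (jitter > 0) {
      # in-plane jitter up to `jitter` voxels; axial and radius jitter are
      # capped at 1 voxel so the tumor always stays inside the brain
      jit <- withSeed(deriveSeed(seed, 202L, i), {
        list(ctr = c(round(runif(2, -jitter, jitter)),
                     round(runif(1, -min(1, jitter), min(1, jitter)))),
             rad = round(runif(1, -min(1, jitter), min(1, jitter))))
      })
      spec_i$tumor_center <- spec_i$tumor_center + jit$ctr
      spec_i$r_core <- max(2, spec_i$r_core + jit$rad)
      spec_i$r_tc <- spec_i$r_core + (base_spec$r_tc - base_spec$r_core)
      spec_i$r_wt <- spec_i$r_tc + (base_spec$r_wt - base_spec$r_tc)
    }
    spec_i$seed <- si
    cs <- generatePhantomCase(spec_i)
    cd <- file.path(out_dir, sprintf("case_%03d", i))
    dir.create(cd, showWarnings = FALSE)
    nm <- sprintf("case_%03d", i)
    suff <- c(T1 = "_t1", T1Gd = "_t1gd", T2 = "_t2", FLAIR = "_flair")
    for (m in MODALITIES) {
      img <- RNifti::asNifti(cs$volume@channels[[m]])
      RNifti::pixdim(img) <- spec_i$spacing
      RNifti::writeNifti(img, file.path(cd, paste0(nm, suff[[m]], ".nii.gz")),
                         datatype = "float")
    }
    saveLabelVolume(cs$labels, cs$volume,
                    file.path(cd, paste0(nm, "_seg.nii.gz")))
    dirs[i] <- cd
  }
  dirs
}

#' Minimum contrast gap of a contrast table
#'
#' Smallest Euclidean distance in 4-channel intensity space between two
#' distinct non-background tissues; the scale against which phantom noise
#' is judged.
#'
#' @param tbl contrast table (modality x tissue)
#' @return numeric scalar
#' @export
minContrastGap <- function(tbl = defaultContrastTable()) {
  tis <- setdiff(colnames(tbl), "background")
  gaps <- c()
  for (i in seq_along(tis)) for (j in seq_len(i - 1L)) {
    gaps <- c(gaps, sqrt(sum((tbl[, tis[i]] - tbl[, tis[j]])^2)))
  }
  min(gaps)
}
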