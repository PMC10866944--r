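#' Default modality filename suffix table
#'
#' BraTS naming drifts across releases (e.g. \code{_t1ce} vs \code{_t1gd});
#' suffixes are matched case-insensitively immediately before the
#' \code{.nii}/\code{.nii.gz} extension, and each modality may list
#' alternatives.
#' @export
defaultSuffixTable <- function() {
  list(T1 = "_t1", T1Gd = c("_t1ce", "_t1gd"), T2 = "_t2",
       FLAIR = "_flair", seg = "_seg")
}

#' Canonical internal orientation code
#'
#' Every volume is reoriented to this code at load so that axial slices are
#' always along the third array axis.
#' @export
CANONICAL_ORIENTATION <- "LAS"

.findModalityFile <- function(files, suffixes) {
  base <- tolower(sub("\\.nii(\\.gz)?$", "", basename(files)))
  hits <- files[Reduce(`|`, lapply(tolower(suffixes),
                                   function(s) endsWith(base, s)))]
  if (length(hits) == 0) return(NA_character_)
  hits[[1]]
}

.readCanonical <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    ori <- RNifti::orientation(img)
    if (!is.na(ori) && !identical(ori, CANONICAL_ORIENTATION))
      RNifti::orientation(img) <- CANONICAL_ORIENTATION
  }
  img
}

#' Load a BraTS-layout case directory
#'
#' Discovers the four modality NIfTI files (and the optional segmentation)
#' by suffix convention, reorients everything to the canonical orientation,
#' and validates geometric consistency. Validation-style cases without a
#' label file are supported.
#'
#' @param case_dir directory containing one case
#' @param suffixes suffix table, see \code{\link{defaultSuffixTable}}
#' @return list with elements \code{volume} (\code{MultimodalVolume}),
#'   \code{labels} (\code{LabelVolume} or NULL) and \code{manifest}
#'   (named file paths)
#' @export
loadCase <- function(case_dir, suffixes = defaultSuffixTable()) {
  stopifnot(dir.exists(case_dir))
  files <- list.files(case_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  manifest <- list()
  imgs <- list()
  for (m in MODALITIES) {
    f <- .findModalityFile(files, suffixes[[m]])
    if (is.na(f))
      stop(sprintf("case %s: missing modality %s (no file with suffix %s)",
                   basename(case_dir), m,
                   paste(suffixes[[m]], collapse = "/")))
    manifest[[m]] <- f
    imgs[[m]] <- .readCanonical(f)
  }
  shapes <- lapply(imgs, dim)
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stop("modality volumes disagree in shape")
  spc <- RNifti::pixdim(imgs[[1]])[1:3]
  aff <- tryCatch(unclass(RNifti::xform(imgs[[1]])), error = function(e) NULL)
  chans <- lapply(imgs, function(i) array(as.numeric(i), dim = dim(i)))
  vol <- MultimodalVolume(chans, spacing = spc, affine = aff,
                          orientation = CANONICAL_ORIENTATION)

  labels <- NULL
  fseg <- .findModalityFile(files, suffixes$seg)
  if (!is.na(fseg)) {
    manifest$seg <- fseg
    seg <- .readCanonical(fseg)
    if (!identical(dim(seg), dim(imgs[[1]])))
      stop("label volume shape does not match image channels")
    segarr <- array(as.integer(round(as.numeric(seg))), dim = dim(seg))
    bad <- setdiff(unique(as.vector(segarr)), BRATS_LABELS)
    if (length(bad))
      stop(sprintf("unknown label values: {%s}",
                   paste(sort(bad), collapse = ",")))
    labels <- LabelVolume(segarr, spacing = spc, affine = aff,
                          orientation = CANONICAL_ORIENTATION)
  }
  list(volume = vol, labels = labels, manifest = manifest)
}

#' Write a case manifest as JSON
#' @param manifest named list of resolved file paths
#' @param path output JSON path
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Map BraTS labels to contiguous class indices
#'
#' The softmax head needs contiguous classes; the bijection is
#' 0->0, 1->1, 2->2, 4->3. \code{indicesToLabels} is its exact inverse.
#'
#' @param labels integer array with values in {0, 1, 2, 4}
#' @return integer array of class indices in {0, 1, 2, 3}
#' @export
labelsToClassIndices <- function(labels) {
  x <- as.integer(labels)
  bad <- setdiff(unique(x), BRATS_LABELS)
  if (length(bad))
    stop(sprintf("labels outside {0,1,2,4}: {%s}",
                 paste(sort(bad), collapse = ",")))
  out <- x
  out[x == 4L] <- 3L
  dim(out) <- dim(labels)
  out
}

#' @rdname labelsToClassIndices
#' @param idx integer array of class indices in {0, 1, 2, 3}
#' @export
indicesToLabels <- function(idx) {
  x <- as.integer(idx)
  bad <- setdiff(unique(x), 0:3)
  if (length(bad))
    stop(sprintf("class indices outside {0,1,2,3}: {%s}",
                 paste(sort(bad), collapse = ",")))
  out <- x
  out[x == 3L] <- 4L
  dim(out) <- dim(idx)
  out
}

#' Derive the nested evaluation regions from a label map
#'
#' ET = enhancing tumor (label 4); TC = tumor core (labels 1 and 4);
#' WT = whole tumor (labels 1, 2 and 4). The nesting ET <= TC <= WT holds
#' by construction; regions are evaluation-only (label 1 vs 2 inside WT is
#' not recoverable from the masks).
#'
#' @param labels a \code{LabelVolume} or an integer array over {0,1,2,4}
#' @return list of logical arrays \code{ET}, \code{TC}, \code{WT}
#' @export
deriveRegions <- function(labels) {
  lab <- if (is(labels, "LabelVolume")) labelArray(labels) else labels
  list(ET = lab == 4L,
       TC = lab == 1L | lab == 4L,
       WT = lab != 0L)
}

#' Save a label volume as a NIfTI prediction file
#'
#' Labels are written as unsigned 8-bit integers with the reference
#' geometry, so that \code{\link{loadCase}} round-trips them bit-exactly.
#'
#' @param labels a \code{LabelVolume} (values in {0,1,2,4})
#' @param reference a \code{MultimodalVolume} or \code{LabelVolume} whose
#'   geometry the prediction must match
#' @param out_path output path (.nii or .nii.gz)
#' @return \code{out_path}, invisibly
#' @export
saveLabelVolume <- function(labels, reference, out_path) {
  stopifnot(is(labels, "LabelVolume"))
  bad <- setdiff(unique(as.integer(labelArray(labels))), BRATS_LABELS)
  if (length(bad))
    stop(sprintf("labels outside {0,1,2,4}: {%s}",
                 paste(sort(bad), collapse = ",")))
  if (!is.null(reference) &&
      !identical(volumeShape(labels), volumeShape(reference)))
    stop("prediction geometry does not match the reference case")
  arr <- labelArray(labels)
  img <- RNifti::asNifti(arr, reference = NULL)
  if (!is.null(labels@affine)) {
    img <- RNifti::`qform<-`(img, structure(labels@affine, code = 2L))
    img <- RNifti::`sform<-`(img, structure(labels@affine, code = 2L))
  }
  RNifti::pixdim(img) <- labels@spacing
  RNifti::writeNifti(img, out_path, datatype = "uint8")
  invisible(out_path)
}
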