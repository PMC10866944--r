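#' Canonical modality order
#'
#' All multimodal arrays in the package use this fixed channel order.
#' @export
MODALITIES <- c("T1", "T1Gd", "T2", "FLAIR")

#' BraTS label alphabet
#'
#' 0 = background/healthy, 1 = necrotic / non-enhancing core,
#' 2 = peritumoral edema, 4 = enhancing tumor.
#' @export
BRATS_LABELS <- c(0L, 1L, 2L, 4L)

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' MultimodalVolume: four co-registered 3D MRI channels with geometry
#'
#' The unit of case-level I/O. Channels are stored in the fixed order
#' T1, T1Gd, T2, FLAIR as 3D numeric arrays sharing one shape; geometry
#' carries voxel spacing (mm), an optional 4x4 NIfTI affine and the
#' anatomical orientation code of the stored axes (axial slices are taken
#' along the third array axis).
#'
#' @slot channels named list of four 3D numeric arrays (T1, T1Gd, T2, FLAIR)
#' @slot spacing numeric length-3 voxel spacing in mm
#' @slot affine 4x4 voxel-to-world matrix, or NULL when synthetic
#' @slot orientation three-letter orientation code (e.g. "LAS")
#' @export
setClass("MultimodalVolume",
  representation(channels = "list", spacing = "numeric",
                 affine = "matrixOrNULL", orientation = "character"))

setValidity("MultimodalVolume", function(object) {
  ch <- object@channels
  if (!identical(names(ch), MODALITIES))
    return(sprintf("channels must be exactly {%s} in order",
                   paste(MODALITIES, collapse = ", ")))
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("every channel must be a 3D array")
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
    return("all channels must share one shape")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  TRUE
})

#' LabelVolume: integer segmentation aligned to a MultimodalVolume
#'
#' Voxel values are restricted to the BraTS alphabet {0, 1, 2, 4}.
#'
#' @slot labels 3D integer array
#' @slot spacing numeric length-3 voxel spacing in mm
#' @slot affine 4x4 voxel-to-world matrix, or NULL
#' @slot orientation three-letter orientation code
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric",
                 affine = "matrixOrNULL", orientation = "character"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  bad <- setdiff(unique(as.integer(object@labels)), BRATS_LABELS)
  if (length(bad))
    return(sprintf("labels outside {0,1,2,4}: {%s}",
                   paste(sort(bad), collapse = ",")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  TRUE
})

#' Construct a MultimodalVolume
#'
#' @param channels named list of 3D arrays with names T1, T1Gd, T2, FLAIR
#'   (any order; stored canonically)
#' @param spacing voxel spacing in mm (default 1 mm isotropic)
#' @param affine optional 4x4 voxel-to-world matrix
#' @param orientation orientation code of the stored axes
#' @return a \code{MultimodalVolume}
#' @export
MultimodalVolume <- function(channels, spacing = c(1, 1, 1), affine = NULL,
                             orientation = "LAS") {
  stopifnot(all(MODALITIES %in% names(channels)))
  new("MultimodalVolume", channels = channels[MODALITIES],
      spacing = as.numeric(spacing), affine = affine,
      orientation = orientation)
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer array over {0, 1, 2, 4}
#' @param spacing voxel spacing in mm
#' @param affine optional 4x4 voxel-to-world matrix
#' @param orientation orientation code
#' @return a \code{LabelVolume}
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                        orientation = "LAS") {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
      affine = affine, orientation = orientation)
}

#' @describeIn MultimodalVolume-class voxel grid shape
#' @param x a volume object
#' @export
setGeneric("volumeShape", function(x) standardGeneric("volumeShape"))

#' @rdname MultimodalVolume-class
#' @export
setMethod("volumeShape", "MultimodalVolume",
          function(x) dim(x@channels[[1]]))

#' @rdname LabelVolume-class
#' @export
setMethod("volumeShape", "LabelVolume", function(x) dim(x@labels))

#' Extract one modality channel
#' @param x a \code{MultimodalVolume}
#' @param modality one of "T1", "T1Gd", "T2", "FLAIR"
#' @return 3D numeric array
#' @export
getChannel <- function(x, modality) {
  stopifnot(is(x, "MultimodalVolume"))
  modality <- match.arg(modality, MODALITIES)
  x@channels[[modality]]
}

#' Voxel spacing accessor
#' @param x a volume object
#' @return numeric length-3, mm per axis
#' @export
voxelSpacing <- function(x) x@spacing

#' Label array accessor
#' @param x a \code{LabelVolume}
#' @return 3D integer array
#' @export
labelArray <- function(x) x@labels

setMethod("show", "MultimodalVolume", function(object) {
  d <- volumeShape(object)
  cat(sprintf("MultimodalVolume: %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              object@orientation))
  for (m in MODALITIES) {
    v <- object@channels[[m]]
    cat(sprintf("  %-5s range [%.3g, %.3g]\n", m, min(v), max(v)))
  }
})

setMethod("show", "LabelVolume", function(object) {
  d <- volumeShape(object)
  tb <- table(factor(object@labels, levels = BRATS_LABELS))
  cat(sprintf("LabelVolume: %d x %d x %d voxels; counts %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                    collapse = " ")))
})

#' Stack the four channels of a volume into one 4D array
#'
#' @param x a \code{MultimodalVolume}
#' @return array [H, W, Z, 4] in canonical channel order
#' @export
channelStack <- function(x) {
  stopifnot(is(x, "MultimodalVolume"))
  d <- volumeShape(x)
  array(unlist(x@channels, use.names = FALSE), dim = c(d, 4L))
}

#' Rebuild a MultimodalVolume from a stacked array
#'
#' @param a array [H, W, Z, 4]
#' @param template volume providing the geometry
#' @return a \code{MultimodalVolume}
#' @export
volumeFromStack <- function(a, template) {
  stopifnot(length(dim(a)) == 4L, dim(a)[4] == 4L)
  ch <- lapply(seq_len(4), function(i) a[, , , i, drop = TRUE])
  names(ch) <- MODALITIES
  for (i in seq_along(ch)) dim(ch[[i]]) <- dim(a)[1:3]
  MultimodalVolume(ch, spacing = template@spacing, affine = template@affine,
                   orientation = template@orientation)
}
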