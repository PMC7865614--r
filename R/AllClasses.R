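#' @import methods
NULL

#' GrayImage: a 2D grayscale brain-slice raster
#'
#' Container for a single-channel intensity image with 8-bit value semantics.
#' Pixels are stored as a numeric matrix (rows x columns) with values in
#' \[0, 255\]; fractional values are allowed internally (interpolation,
#' rescaling) and are only quantized on serialization to 8-bit formats.
#' Coordinates throughout the package are 0-based \code{(row, col)}; for an
#' image of even width W the vertical mirror axis lies between columns
#' \code{W/2 - 1} and \code{W/2}.
#'
#' @slot pixels numeric matrix of intensities in \[0, 255\].
#' @slot sourceId character identifier (file path or synthetic id).
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", sourceId = "character"),
  prototype(pixels = matrix(0, 1, 1), sourceId = NA_character_)
)

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (length(p) < 1L) return("pixels must be non-empty")
  if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0, 255]")
  if (length(object@sourceId) != 1L) return("sourceId must be length 1")
  TRUE
})

#' BinaryMask: a 0/1 raster produced by thresholding
#'
#' @slot pixels numeric matrix with values exactly 0 or 1.
#' @slot thresholdUsed the intensity threshold that produced the mask.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", thresholdUsed = "numeric"),
  prototype(pixels = matrix(0, 1, 1), thresholdUsed = NA_real_)
)

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (!all(p == 0 | p == 1)) return("mask values must be exactly 0 or 1")
  TRUE
})

#' AlignmentResult: parameters placing the brain midline on the image midline
#'
#' Records the centroid found on the binarized slice, the translation applied
#' to move it to the geometric image center, the rotation angle (degrees,
#' counter-clockwise positive) minimizing the mirror-symmetry objective, and
#' the value of that objective at the optimum.
#'
#' @slot centroidRow,centroidCol centroid of the brain mask (0-based pixels).
#' @slot shiftRow,shiftCol translation applied (pixels).
#' @slot angleDeg rotation applied (degrees, CCW positive).
#' @slot symmetryScore mean squared mirror difference at the optimum.
#' @export
setClass("AlignmentResult",
  representation(
    centroidRow = "numeric", centroidCol = "numeric",
    shiftRow = "numeric", shiftCol = "numeric",
    angleDeg = "numeric", symmetryScore = "numeric"
  )
)

setValidity("AlignmentResult", function(object) {
  if (object@symmetryScore < 0) return("symmetryScore must be >= 0")
  TRUE
})

#' AsymmetryMap: pixelwise mirror-difference image
#'
#' The saturating two-way subtraction of an aligned slice and its vertical
#' mirror, equal elementwise to |I - mirror(I)|. Bilaterally symmetric pixels
#' are exactly 0.
#'
#' @slot pixels numeric matrix in \[0, 255\].
#' @slot parentId identifier of the aligned image the map was derived from.
#' @export
setClass("AsymmetryMap",
  representation(pixels = "matrix", parentId = "character"),
  prototype(pixels = matrix(0, 1, 1), parentId = NA_character_)
)

setValidity("AsymmetryMap", function(object) {
  p <- object@pixels
  if (anyNA(p) || min(p) < 0 || max(p) > 255) {
    return("map values must lie in [0, 255]")
  }
  TRUE
})

#' Codebook: K-Means visual vocabulary over local descriptors
#'
#' @slot centers k x d matrix of cluster centers in descriptor space.
#' @slot k vocabulary size.
#' @slot descriptorDim descriptor dimensionality (64 for the SURF-like
#'   descriptors used here).
#' @slot seed RNG seed the codebook was fitted with.
#' @export
setClass("Codebook",
  representation(centers = "matrix", k = "integer",
                 descriptorDim = "integer", seed = "integer")
)

setValidity("Codebook", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (nrow(object@centers) != object@k) return("centers must have k rows")
  if (ncol(object@centers) != object@descriptorDim) {
    return("centers must have descriptorDim columns")
  }
  if (anyDuplicated(object@centers) > 0) return("centers must be distinct")
  TRUE
})

#' CVReport: repeated stratified cross-validation results for one model
#'
#' @slot model model name (one of the eight supported specifications).
#' @slot dataset label of the binary dataset, e.g. "AD vs. NC".
#' @slot runs,folds protocol dimensions.
#' @slot perFold data.frame of per-fold confusion counts (run, fold, TP, FP,
#'   TN, FN).
#' @slot accuracy,sensitivity,specificity mean over all folds of all runs (%).
#' @slot accuracySd,sensitivitySd,specificitySd sd over run means (%).
#' @slot rocPoints data.frame with columns fpr, tpr.
#' @slot auc area under the ROC curve from pooled out-of-fold scores.
#' @slot seed master seed.
#' @export
setClass("CVReport",
  representation(
    model = "character", dataset = "character",
    runs = "integer", folds = "integer",
    perFold = "data.frame",
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    accuracySd = "numeric", sensitivitySd = "numeric",
    specificitySd = "numeric",
    rocPoints = "data.frame", auc = "numeric", seed = "integer"
  )
)

setValidity("CVReport", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' PhantomBundle: a rendered synthetic brain slice plus ground truth
#'
#' @slot image the rendered GrayImage (after pose perturbation and noise).
#' @slot truthMaskTissue BinaryMask of the tissue ellipse in the unposed
#'   frame.
#' @slot truthLesions data.frame (row, col, radius, amplitude) of inserted
#'   unilateral lesions, unposed 0-based coordinates.
#' @slot truthPose list(rotation_deg, shift) applied after rendering.
#' @slot spec the list of generator parameters (label, amplitude, seed, ...).
#' @export
setClass("PhantomBundle",
  representation(
    image = "GrayImage", truthMaskTissue = "BinaryMask",
    truthLesions = "data.frame", truthPose = "list", spec = "list"
  )
)

## ---- constructors ----------------------------------------------------------

#' Create a GrayImage from a numeric matrix
#'
#' @param pixels numeric matrix with values in \[0, 255\] (rows x columns).
#' @param sourceId identifier carried through the pipeline.
#' @return A \linkS4class{GrayImage}.
#' @export
GrayImage <- function(pixels, sourceId = NA_character_) {
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, sourceId = as.character(sourceId))
}

#' Create an AsymmetryMap from a numeric matrix
#'
#' @param pixels numeric matrix in \[0, 255\].
#' @param parentId identifier of the aligned parent image.
#' @return An \linkS4class{AsymmetryMap}.
#' @export
AsymmetryMap <- function(pixels, parentId = NA_character_) {
  storage.mode(pixels) <- "double"
  new("AsymmetryMap", pixels = pixels, parentId = as.character(parentId))
}

## ---- accessors and show ----------------------------------------------------

#' Extract the pixel matrix of an image-like object
#'
#' @param x a GrayImage, BinaryMask or AsymmetryMap.
#' @return The numeric pixel matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "AsymmetryMap", function(x) x@pixels)

#' Source identifier of an image
#'
#' @param x a GrayImage or AsymmetryMap.
#' @return Character identifier.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname sourceId
#' @export
setMethod("sourceId", "GrayImage", function(x) x@sourceId)

#' @rdname sourceId
#' @export
setMethod("sourceId", "AsymmetryMap", function(x) x@parentId)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setMethod("dim", "AsymmetryMap", function(x) dim(x@pixels))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %dx%d [%s]\n  intensity range [%.2f, %.2f]\n",
              nrow(p), ncol(p),
              ifelse(is.na(object@sourceId), "<unnamed>", object@sourceId),
              min(p), max(p)))
})

setMethod("show", "AsymmetryMap", function(object) {
  p <- object@pixels
  cat(sprintf(
    "AsymmetryMap %dx%d [parent %s]\n  %.1f%% nonzero, max %.2f\n",
    nrow(p), ncol(p),
    ifelse(is.na(object@parentId), "<unnamed>", object@parentId),
    100 * mean(p != 0), max(p)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    paste0("AlignmentResult\n  centroid (%.2f, %.2f)  shift (%.2f, %.2f)\n",
           "  angle %.2f deg  symmetry score %.4f\n"),
    object@centroidRow, object@centroidCol,
    object@shiftRow, object@shiftCol,
    object@angleDeg, object@symmetryScore))
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: k=%d, descriptor dim %d, seed %d\n",
              object@k, object@descriptorDim, object@seed))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf(
    paste0("CVReport %s on %s (%d runs x %d folds)\n",
           "  accuracy %.1f%% (sd %.1f)  sensitivity %.1f%%  ",
           "specificity %.1f%%  AUC %.3f\n"),
    object@model, object@dataset, object@runs, object@folds,
    object@accuracy, object@accuracySd, object@sensitivity,
    object@specificity, object@auc))
})

setMethod("show", "PhantomBundle", function(object) {
  cat(sprintf(
    "PhantomBundle [%s] label=%s amplitude=%.1f lesions=%d seed=%d\n",
    object@image@sourceId, object@spec$label,
    object@spec$asymmetry_amplitude, nrow(object@truthLesions),
    object@spec$seed))
})

#' Rotation angle of an alignment
#' @param x an AlignmentResult.
#' @return Numeric angle in degrees (CCW positive).
#' @export
angleDeg <- function(x) {
  stopifnot(is(x, "AlignmentResult"))
  x@angleDeg
}

#' Translation applied by an alignment
#' @param x an AlignmentResult.
#' @return Numeric length-2 vector (shift_row, shift_col) in pixels.
#' @export
shiftRC <- function(x) {
  stopifnot(is(x, "AlignmentResult"))
  c(x@shiftRow, x@shiftCol)
}
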