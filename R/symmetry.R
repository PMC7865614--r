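# Symmetry-axis detection and asymmetry-map extraction.
#
# The working hypothesis is that a brain slice has an axis of reflective
# symmetry through its center: the slice is binarized, its centroid is
# translated to the image center, and the in-plane rotation minimizing the
# mirror-difference objective is found by exhaustive grid search. The
# asymmetry map is then the saturating two-way subtraction of the aligned
# slice and its vertical mirror.

#' Binarize a grayscale slice
#'
#' Pixels strictly above the threshold become 1, all others 0. With
#' \code{threshold = "auto"} an Otsu threshold is computed on the histogram
#' of nonzero pixels only (the zero background of a stripped slice would
#' otherwise dominate the histogram).
#'
#' @param img a \linkS4class{GrayImage}.
#' @param threshold numeric intensity in \[0, 255\], or \code{"auto"}.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(img, threshold = "auto") {
  stopifnot(is(img, "GrayImage"))
  M <- img@pixels
  if (all(M == 0)) stop("binarize: empty image")
  if (identical(threshold, "auto")) {
    threshold <- .otsu_threshold(M[M > 0])
  }
  new("BinaryMask", pixels = (M > threshold) * 1,
      thresholdUsed = as.numeric(threshold))
}

# Otsu's threshold on a 256-bin histogram of intensities in [0, 255].
# Returns the bin value maximizing between-class variance (first maximum).
.otsu_threshold <- function(v) {
  counts <- tabulate(pmin(floor(v), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels[which.max(sigma_b)]
}

#' Centroid of a brain mask
#'
#' Unweighted: the mean 0-based (row, col) of nonzero mask pixels. With
#' \code{weights} supplied, the intensity-weighted mean (center of mass)
#' over all pixels of the weight image.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param weights optional \linkS4class{GrayImage} of intensity weights.
#' @return Numeric length-2 vector (row, col).
#' @export
maskCentroid <- function(mask, weights = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  W <- if (is.null(weights)) mask@pixels else pixels(weights)
  tot <- sum(W)
  if (tot == 0) stop("maskCentroid: empty mask")
  g <- .coord_grid(nrow(W), ncol(W))
  c(sum(g$r * as.vector(W)), sum(g$c * as.vector(W))) / tot
}

#' Mirror-symmetry objective
#'
#' Mean squared difference between an image and its vertical mirror,
#' computed over the union support (pixels where the image or its mirror is
#' nonzero). Zero iff the image is perfectly mirror-symmetric on that
#' support.
#'
#' @param img a \linkS4class{GrayImage}.
#' @return Non-negative scalar.
#' @export
symmetryObjective <- function(img) {
  M <- pixels(img)
  if (all(M == 0)) stop("symmetryObjective: blank image")
  R <- .mirror_mat(M)
  support <- M != 0 | R != 0
  mean((M[support] - R[support])^2)
}

#' Find the rotation maximizing mirror symmetry
#'
#' Exhaustive grid search over angles in \code{[-range_deg, +range_deg]}
#' spaced \code{step_deg} apart: the image (assumed centroid-centered) is
#' rotated about its center with bilinear interpolation and the angle
#' minimizing \code{\link{symmetryObjective}} is returned. Ties are broken
#' toward the smallest |angle|, then toward the negative angle.
#'
#' @param img a centroid-centered \linkS4class{GrayImage}.
#' @param range_deg half-width of the search range in degrees (default 15).
#' @param step_deg grid step in degrees (default 0.5).
#' @return List with \code{angle} (degrees) and \code{score} (objective at
#'   the optimum).
#' @export
findSymmetryRotation <- function(img, range_deg = 15, step_deg = 0.5) {
  stopifnot(is(img, "GrayImage"))
  M <- img@pixels
  if (all(M == 0)) stop("findSymmetryRotation: blank image")
  angles <- seq(-range_deg, range_deg, by = step_deg)
  # tie-break order: |angle| ascending, negative before positive
  angles <- angles[order(abs(angles), angles)]
  scores <- vapply(angles, function(a) {
    symmetryObjective(GrayImage(.rotate_mat(M, a)))
  }, numeric(1))
  best <- which.min(scores)
  list(angle = angles[best], score = scores[best])
}

#' Asymmetry map by mirrored-hemisphere subtraction
#'
#' With \code{R = mirror(I)}, computes the two-way saturating difference
#' \code{clip0(I - R) + clip0(R - I)}, i.e. the left-minus-right and
#' right-minus-left hemisphere subtractions added after flooring each at
#' zero (8-bit saturating arithmetic). This equals \code{|I - R|}
#' elementwise, so bilaterally symmetric pixels are exactly 0.
#'
#' @param img a symmetry-aligned \linkS4class{GrayImage}.
#' @return An \linkS4class{AsymmetryMap}.
#' @export
asymmetryMap <- function(img) {
  stopifnot(is(img, "GrayImage"))
  M <- img@pixels
  R <- .mirror_mat(M)
  D <- pmax(M - R, 0) + pmax(R - M, 0)
  AsymmetryMap(D, parentId = img@sourceId)
}

#' Align a slice to its symmetry axis and extract the asymmetry map
#'
#' Composes the full alignment chain: binarize, centroid, translation of
#' the centroid to the image center, rotation search, rotation, and
#' asymmetry-map extraction.
#'
#' @param img a skull-stripped \linkS4class{GrayImage}.
#' @param threshold binarization threshold for the centroid mask. The
#'   default 0 takes the whole nonzero footprint of the stripped slice as
#'   the brain mask (the footprint centroid is the brain center);
#'   \code{"auto"} (Otsu on nonzero pixels) is appropriate for slices whose
#'   background is not already zeroed.
#' @param angle_range,angle_step rotation search parameters (degrees).
#' @param weighted_centroid use the intensity-weighted centroid instead of
#'   the binary-mask centroid.
#' @return List with elements \code{aligned} (GrayImage), \code{map}
#'   (AsymmetryMap) and \code{alignment} (AlignmentResult).
#' @export
alignAndExtract <- function(img, threshold = 0,
                            angle_range = 15, angle_step = 0.5,
                            weighted_centroid = FALSE) {
  stopifnot(is(img, "GrayImage"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("alignAndExtract [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mask <- stage("binarize", binarize(img, threshold))
  ctr <- stage("centroid",
               maskCentroid(mask, weights = if (weighted_centroid) img))
  centered <- stage("translate", translateToCenter(img, ctr))
  shift <- attr(centered, "shift")
  rot <- stage("rotation-search",
               findSymmetryRotation(centered, angle_range, angle_step))
  aligned <- stage("rotate", rotateImage(centered, rot$angle))
  map <- stage("asymmetry-map", asymmetryMap(aligned))
  alignment <- new("AlignmentResult",
    centroidRow = ctr[1], centroidCol = ctr[2],
    shiftRow = shift[1], shiftCol = shift[2],
    angleDeg = rot$angle, symmetryScore = rot$score)
  list(aligned = aligned, map = map, alignment = alignment)
}
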