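# Reading, standardizing and skull-stripping 2D brain-slice images.

#' Load a 2D brain-slice image as a GrayImage
#'
#' Reads PNG, JPEG or TIFF rasters, or a single slice out of a NIfTI volume.
#' RGB inputs are collapsed to one channel by averaging; 16-bit (or any
#' non-8-bit) integer data are linearly rescaled so the format maximum maps
#' to 255. NIfTI volumes are windowed by their own min/max to \[0, 255\] and
#' require a slice index.
#'
#' @param path path to a .png/.jpg/.jpeg/.tif/.tiff/.nii/.nii.gz file.
#' @param slice_index for NIfTI input: 1-based index of the slice to extract.
#' @param slice_axis for NIfTI input: axis (1, 2 or 3) perpendicular to the
#'   extracted slice; default 3 (axial for RAS-like volumes).
#' @return A \linkS4class{GrayImage} with intensities in \[0, 255\].
#' @export
loadImage <- function(path, slice_index = NULL, slice_axis = 3) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  M <- switch(ext,
    png  = .collapse_channels(png::readPNG(path)) * 255,
    jpg  = ,
    jpeg = .collapse_channels(jpeg::readJPEG(path)) * 255,
    tif  = ,
    tiff = .collapse_channels(tiff::readTIFF(path)) * 255,
    nii  = .load_nifti_slice(path, slice_index, slice_axis),
    stop("unsupported image format: ", path)
  )
  GrayImage(pmin(pmax(M, 0), 255), sourceId = path)
}

# png/jpeg/tiff readers return arrays in [0,1], possibly H x W x C.
.collapse_channels <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3)  # ignore an alpha channel if present
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  a
}

.load_nifti_slice <- function(path, slice_index, slice_axis) {
  if (is.null(slice_index)) {
    stop("NIfTI input requires a slice index (slice_index/--slice-index)")
  }
  vol <- RNifti::asNifti(RNifti::readNifti(path))
  arr <- as.array(vol)
  if (length(dim(arr)) < 3) arr <- array(arr, dim = c(dim(arr), 1))
  M <- switch(as.character(slice_axis),
    "1" = arr[slice_index, , ],
    "2" = arr[, slice_index, ],
    "3" = arr[, , slice_index],
    stop("slice_axis must be 1, 2 or 3"))
  M <- as.matrix(M)
  rng <- range(M)
  if (rng[2] > rng[1]) M <- (M - rng[1]) / (rng[2] - rng[1]) * 255 else M[] <- 0
  M
}

#' Write a GrayImage (or AsymmetryMap) as an 8-bit PNG
#'
#' Values are rounded to the nearest integer in \[0, 255\]. Loading the file
#' back reproduces integer-valued images bit-exactly.
#'
#' @param img a \linkS4class{GrayImage} or \linkS4class{AsymmetryMap}.
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  M <- pixels(img)
  png::writePNG(round(M) / 255, target = path)
  invisible(path)
}

#' Standardize a slice: min-max normalize and resize to a square raster
#'
#' Resamples to \code{size} x \code{size} with bilinear interpolation, then
#' rescales intensities so they span exactly \[0, 255\] (a constant image
#' maps to all zeros). Idempotent on already-standardized images.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param size output edge length in pixels (default 256).
#' @return Standardized \linkS4class{GrayImage}.
#' @export
normalizeResize <- function(img, size = 256) {
  stopifnot(is(img, "GrayImage"))
  M <- .resize_mat(img@pixels, size, size)
  rng <- range(M)
  if (rng[2] > rng[1]) {
    M <- (M - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    M[] <- 0
  }
  GrayImage(M, sourceId = img@sourceId)
}

#' Remove skull and background by intensity banding
#'
#' Retains pixels whose intensity lies inside \code{[lower, upper]} and zeros
#' all others, then keeps only the largest 8-connected surviving component
#' (smaller islands, typically skull fragments, are zeroed). This automated
#' stand-in for manual threshold segmentation is deliberately simple and can
#' be swapped for dedicated brain-extraction software upstream.
#'
#' @param img a standardized \linkS4class{GrayImage}.
#' @param band numeric length-2 \code{c(lower, upper)} with
#'   \code{lower < upper}, intensities in \[0, 255\].
#' @return Skull-stripped \linkS4class{GrayImage}.
#' @export
skullStrip <- function(img, band) {
  stopifnot(is(img, "GrayImage"), length(band) == 2)
  if (!(band[1] < band[2])) stop("threshold band requires lower < upper")
  M <- img@pixels
  inband <- M >= band[1] & M <= band[2]
  if (!any(inband)) stop("empty brain mask: no pixel inside threshold band")
  keep <- .largest_component8(inband)
  M[!keep] <- 0
  GrayImage(M, sourceId = img@sourceId)
}

# Largest 8-connected component of a logical mask. EBImage::bwlabel is
# 4-connected, so 4-connected labels touching diagonally are merged with a
# small union-find pass.
.largest_component8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab == 1L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  H <- nrow(lab); W <- ncol(lab)
  for (dc in c(-1L, 1L)) {  # diagonal neighbors (down-left, down-right)
    a <- lab[1:(H - 1), if (dc == 1L) 2:W else 1:(W - 1)]
    b <- lab[2:H, if (dc == 1L) 1:(W - 1) else 2:W]
    pairs <- unique(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]))
    if (length(pairs)) {
      for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sizes <- tapply(tabulate(lab[lab > 0], n), root, sum)
  best <- as.integer(names(sizes)[which.max(sizes)])
  matrix(root[pmax(lab, 1L)] == best & lab > 0L, H, W)
}
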