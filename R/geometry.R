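# Geometric resampling primitives shared by alignment, resizing and the
# phantom generator. All coordinates are 0-based (row, col); the geometric
# center of an H x W image is ((H-1)/2, (W-1)/2).

# Bilinear sample of matrix M at real-valued 0-based coordinates (rr, cc).
# Points outside the raster contribute `fill` (zero fill for rigid motions,
# edge clamping is handled by the caller for resizing).
.bilinear_sample <- function(M, rr, cc, fill = 0) {
  H <- nrow(M); W <- ncol(M)
  r0 <- floor(rr); c0 <- floor(cc)
  dr <- rr - r0; dc <- cc - c0
  fetch <- function(r, c) {
    ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
    v <- rep(fill, length(r))
    if (any(ok)) v[ok] <- M[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  fetch(r0, c0) * (1 - dr) * (1 - dc) +
    fetch(r0, c0 + 1) * (1 - dr) * dc +
    fetch(r0 + 1, c0) * dr * (1 - dc) +
    fetch(r0 + 1, c0 + 1) * dr * dc
}

# Full 0-based coordinate grid of an H x W image, as two H*W vectors.
.coord_grid <- function(H, W) {
  list(r = rep(seq_len(H) - 1, times = W),
       c = rep(seq_len(W) - 1, each = H))
}

#' Mirror an image across its vertical midline
#'
#' Reverses column order. An involution: applying it twice restores the
#' input exactly.
#'
#' @param img a \linkS4class{GrayImage} (or numeric matrix).
#' @return Object of the same type with columns reversed.
#' @export
mirrorVertical <- function(img) {
  if (is(img, "GrayImage")) {
    return(GrayImage(.mirror_mat(img@pixels), sourceId = img@sourceId))
  }
  if (is(img, "AsymmetryMap")) {
    return(AsymmetryMap(.mirror_mat(img@pixels), parentId = img@parentId))
  }
  .mirror_mat(img)
}

.mirror_mat <- function(M) M[, rev(seq_len(ncol(M))), drop = FALSE]

#' Translate an image so a given point lands on the image center
#'
#' Shifts the raster so that point \code{c = (row, col)} maps to the
#' geometric center \code{((H-1)/2, (W-1)/2)}. Vacated pixels are zero;
#' subpixel shifts use bilinear interpolation (integer shifts are exact).
#'
#' @param img a \linkS4class{GrayImage}.
#' @param centre numeric length-2: the 0-based (row, col) point to center.
#' @return Shifted \linkS4class{GrayImage}, plus the applied shift in
#'   attribute \code{"shift"} (rows, cols).
#' @export
translateToCenter <- function(img, centre) {
  stopifnot(is(img, "GrayImage"), length(centre) == 2)
  M <- img@pixels
  H <- nrow(M); W <- ncol(M)
  shift <- c((H - 1) / 2 - centre[1], (W - 1) / 2 - centre[2])
  if (any(abs(shift) > c(H, W))) {
    stop("translateToCenter: shift magnitude exceeds image size")
  }
  out <- GrayImage(.translate_mat(M, shift), sourceId = img@sourceId)
  attr(out, "shift") <- shift
  out
}

.translate_mat <- function(M, shift) {
  if (all(shift == 0)) return(M)
  H <- nrow(M); W <- ncol(M)
  g <- .coord_grid(H, W)
  v <- .bilinear_sample(M, g$r - shift[1], g$c - shift[2])
  matrix(pmin(pmax(v, 0), 255), H, W)
}

#' Rotate an image about its geometric center
#'
#' Rigid rotation by \code{angle_deg} degrees, counter-clockwise positive,
#' about \code{((H-1)/2, (W-1)/2)}, with bilinear interpolation and zero
#' fill. An angle of exactly 0 is an identity (no resampling).
#'
#' @param img a \linkS4class{GrayImage}.
#' @param angle_deg rotation angle in degrees.
#' @return Rotated \linkS4class{GrayImage}.
#' @export
rotateImage <- function(img, angle_deg) {
  stopifnot(is(img, "GrayImage"))
  GrayImage(.rotate_mat(img@pixels, angle_deg), sourceId = img@sourceId)
}

.rotate_mat <- function(M, angle_deg) {
  if (angle_deg == 0) return(M)
  H <- nrow(M); W <- ncol(M)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  th <- angle_deg * pi / 180
  g <- .coord_grid(H, W)
  dr <- g$r - cr; dc <- g$c - cc
  # inverse mapping: output pixel pulled from input rotated by -angle
  sr <- cr + cos(th) * dr + sin(th) * dc
  sc <- cc - sin(th) * dr + cos(th) * dc
  v <- .bilinear_sample(M, sr, sc)
  matrix(pmin(pmax(v, 0), 255), H, W)
}

# Bilinear resize with pixel-center alignment and edge clamping.
.resize_mat <- function(M, H_out, W_out) {
  H <- nrow(M); W <- ncol(M)
  if (H == H_out && W == W_out) return(M)
  r_out <- rep(seq_len(H_out) - 1, times = W_out)
  c_out <- rep(seq_len(W_out) - 1, each = H_out)
  sr <- (r_out + 0.5) * H / H_out - 0.5
  sc <- (c_out + 0.5) * W / W_out - 0.5
  sr <- pmin(pmax(sr, 0), H - 1)
  sc <- pmin(pmax(sc, 0), W - 1)
  matrix(.bilinear_sample(M, sr, sc), H_out, W_out)
}
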