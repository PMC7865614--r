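# Bag-of-visual-words encoding of asymmetry maps.
#
# Interest points are found with a determinant-of-Hessian blob detector over
# a small scale pyramid (the detection principle behind SURF); each keypoint
# yields a 64-dimensional descriptor built from sums of horizontal/vertical
# gradients and their absolute values over a 4x4 grid of subregions (the
# SURF descriptor layout). Descriptors are quantized against a K-Means
# codebook (k-means++ initialization, fixed seed) and each image is encoded
# as the L1-normalized histogram of its descriptor-to-center assignments.

# Separable Gaussian smoothing (reflect padding at the border).
.gauss_smooth <- function(M, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(X) {  # convolve columns of X with k
    n <- nrow(X)
    Xp <- rbind(X[r:1, , drop = FALSE], X, X[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(X))
    for (i in seq_along(k)) {
      out <- out + k[i] * Xp[i:(i + n - 1), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(M))))
}

# central differences with replicated borders
.grad_row <- function(M) {
  (rbind(M[-1, , drop = FALSE], M[nrow(M), ]) -
     rbind(M[1, ], M[-nrow(M), , drop = FALSE])) / 2
}
.grad_col <- function(M) t(.grad_row(t(M)))

#' Detect blob-like interest points on an asymmetry map
#'
#' Scale-normalized determinant-of-Hessian detector: the map is smoothed at
#' each scale in \code{sigmas}, second derivatives are taken by finite
#' differences, and local maxima of \code{sigma^4 * det(Hessian)} above
#' \code{threshold} within their 3x3 neighborhood are kept. The strongest
#' \code{retain} fraction across scales is returned.
#'
#' @param map an \linkS4class{AsymmetryMap} (or matrix/GrayImage).
#' @param sigmas numeric vector of detection scales in pixels.
#' @param threshold minimum scale-normalized DoH response.
#' @param retain fraction of strongest keypoints kept (default 0.8).
#' @return data.frame (row, col, sigma, response), 0-based coordinates.
#' @export
detectKeypoints <- function(map, sigmas = c(2, 4, 8), threshold = 1,
                            retain = 0.8) {
  M <- if (is.matrix(map)) map else pixels(map)
  out <- list()
  for (s in sigmas) {
    G <- .gauss_smooth(M, s)
    Gr <- .grad_row(G); Gc <- .grad_col(G)
    Lrr <- .grad_row(Gr); Lcc <- .grad_col(Gc); Lrc <- .grad_col(Gr)
    doh <- s^4 * (Lrr * Lcc - Lrc^2)
    H <- nrow(doh); W <- ncol(doh)
    inner <- doh[2:(H - 1), 2:(W - 1)]
    is_max <- inner > threshold
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max &
        inner >= doh[2:(H - 1) + dr, 2:(W - 1) + dc]
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1]] <- data.frame(
        row = idx[, 1], col = idx[, 2], sigma = s,
        response = inner[is_max])  # 0-based: inner row i is image row i+1
    }
  }
  if (!length(out)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      sigma = numeric(0), response = numeric(0)))
  }
  kp <- do.call(rbind, out)
  kp <- kp[order(-kp$response), , drop = FALSE]
  kp <- kp[seq_len(max(1L, floor(retain * nrow(kp)))), , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

#' Dense keypoint grid (fallback when blob detection finds too few points)
#'
#' @param map an \linkS4class{AsymmetryMap} (or matrix/GrayImage).
#' @param stride grid spacing in pixels.
#' @param sigma nominal scale attached to each grid point.
#' @return data.frame (row, col, sigma, response).
#' @export
denseKeypoints <- function(map, stride = 16, sigma = 4) {
  M <- if (is.matrix(map)) map else pixels(map)
  margin <- ceiling(2.5 * sigma)
  rs <- seq(margin, nrow(M) - 1 - margin, by = stride)
  cs <- seq(margin, ncol(M) - 1 - margin, by = stride)
  expand.grid(row = rs, col = cs, sigma = sigma, response = Inf)
}

# 64-dim SURF-style descriptor at one keypoint: a 16x16 sample grid spaced
# sigma/2 apart is split into 4x4 subregions; each contributes
# (sum dc, sum dr, sum |dc|, sum |dr|). L2-normalized.
.surf_descriptor <- function(M, Gr, Gc, row, col, sigma) {
  spacing <- sigma / 2
  offs <- (seq_len(16) - 8.5) * spacing
  rr <- rep(row + offs, times = 16)
  cc <- rep(col + offs, each = 16)
  dr <- .bilinear_sample(Gr, rr, cc)
  dc <- .bilinear_sample(Gc, rr, cc)
  block <- rep(rep(1:4, each = 4), times = 16) +
    4 * (rep(rep(1:4, each = 4), each = 16) - 1)  # 1..16 subregion index
  d <- c(vapply(1:16, function(b) {
    i <- block == b
    c(sum(dc[i]), sum(dr[i]), sum(abs(dc[i])), sum(abs(dr[i])))
  }, numeric(4)))
  n <- sqrt(sum(d^2))
  if (n > 0) d / n else d
}

#' Compute SURF-like descriptors for a map
#'
#' @param map an \linkS4class{AsymmetryMap} (or matrix/GrayImage).
#' @param keypoints data.frame from \code{\link{detectKeypoints}} or
#'   \code{\link{denseKeypoints}}; if NULL, blob detection is attempted
#'   and the dense grid is used when it yields fewer than \code{min_kp}.
#' @param min_kp minimum keypoint count before falling back to the dense
#'   grid.
#' @return numeric matrix, one 64-dim row per keypoint (0 rows possible).
#' @export
surfDescriptors <- function(map, keypoints = NULL, min_kp = 5) {
  M <- if (is.matrix(map)) map else pixels(map)
  if (is.null(keypoints)) {
    keypoints <- detectKeypoints(M)
    if (nrow(keypoints) < min_kp) keypoints <- denseKeypoints(M)
  }
  if (!nrow(keypoints)) return(matrix(numeric(0), 0, 64))
  G <- .gauss_smooth(M, 1)
  Gr <- .grad_row(G); Gc <- .grad_col(G)
  t(mapply(function(r, c, s) .surf_descriptor(M, Gr, Gc, r, c, s),
           keypoints$row, keypoints$col, keypoints$sigma))
}

# k-means++ seeding (deterministic given the RNG state)
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      remaining <- setdiff(seq_len(n), centers[seq_len(j - 1)])
      centers[j] <- if (length(remaining)) remaining[1] else centers[1]
    } else {
      centers[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums((X - matrix(X[centers[j], ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  X[centers, , drop = FALSE]
}

#' Fit a visual-word codebook over a corpus of asymmetry maps
#'
#' Pools descriptors from all maps and clusters them with K-Means
#' (k-means++ initialization, Lloyd iterations, fixed seed). Identical
#' seeds give bit-identical codebooks.
#'
#' @param maps list of \linkS4class{AsymmetryMap}s (or matrices).
#' @param k vocabulary size (default 500).
#' @param seed integer RNG seed.
#' @param descriptors optional pre-computed descriptor matrix (pooled);
#'   when supplied, \code{maps} is ignored.
#' @return A \linkS4class{Codebook}.
#' @export
bofFit <- function(maps, k = 500, seed = 42, descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- do.call(rbind, lapply(maps, surfDescriptors))
  }
  if (is.null(descriptors) || nrow(descriptors) < k) {
    stop("bofFit: fewer descriptors (", NROW(descriptors),
         ") than vocabulary size k=", k,
         "; use denseKeypoints() for a dense-grid fallback or reduce k")
  }
  descriptors <- unique(descriptors)
  if (nrow(descriptors) < k) {
    stop("bofFit: fewer than k distinct descriptors; duplicate centers ",
         "would result — reduce k")
  }
  centers <- withr::with_seed(seed, {
    init <- .kmeanspp_init(descriptors, k)
    km <- suppressWarnings(
      stats::kmeans(descriptors, centers = init, iter.max = 100,
                    algorithm = "Lloyd"))
    km$centers
  })
  dimnames(centers) <- NULL
  new("Codebook", centers = centers, k = as.integer(k),
      descriptorDim = ncol(descriptors), seed = as.integer(seed))
}

#' Encode a map as a visual-word occurrence histogram
#'
#' Assigns each descriptor to its nearest codebook center (Euclidean) and
#' returns the L1-normalized assignment histogram. A map with no
#' descriptors yields a uniform histogram with a warning.
#'
#' @param map an \linkS4class{AsymmetryMap} (or matrix), or a descriptor
#'   matrix via \code{descriptors}.
#' @param codebook a fitted \linkS4class{Codebook}.
#' @param descriptors optional pre-computed descriptors for this map.
#' @return Numeric vector of length k summing to 1.
#' @export
bofEncode <- function(map, codebook, descriptors = NULL) {
  stopifnot(is(codebook, "Codebook"))
  if (is.null(descriptors)) descriptors <- surfDescriptors(map)
  k <- codebook@k
  if (!nrow(descriptors)) {
    warning("bofEncode: no descriptors; returning uniform histogram")
    return(rep(1 / k, k))
  }
  if (ncol(descriptors) != codebook@descriptorDim) {
    stop("bofEncode: descriptor dimension ", ncol(descriptors),
         " does not match codebook (", codebook@descriptorDim, ")")
  }
  assign <- .nearest_center(descriptors, codebook@centers)
  h <- tabulate(assign, nbins = k)
  h / sum(h)
}

# index of nearest center for each row of X (Euclidean, exhaustive)
.nearest_center <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) -
    2 * X %*% t(C) + outer(rep(1, nrow(X)), rowSums(C^2))
  max.col(-d2, ties.method = "first")
}
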