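# Statistical texture features of asymmetry maps.
#
# Nine of the ten statistics are computed on the approximation subband of a
# 2D discrete wavelet transform of the map (Haar by default); the exception
# is the mirror MSE, computed directly from the aligned slice and its
# vertical mirror without any wavelet transform. Population (biased) moment
# estimators are used throughout; kurtosis is non-excess (Gaussian -> 3).

STAT_FEATURE_NAMES <- c("MSE", "Mean", "Std", "Entropy", "RMS", "Variance",
                        "Smoothness", "Kurtosis", "Skewness", "IDM")

#' Mean squared error between a slice and its mirror
#'
#' Mean over all pixels of the squared intensity difference. Applied to an
#' aligned slice and its vertical mirror this quantifies total hemispheric
#' asymmetry; it is the one feature computed without a wavelet transform.
#'
#' @param original a \linkS4class{GrayImage}.
#' @param mirrored its mirrored counterpart (same dimensions).
#' @return Non-negative scalar.
#' @export
mirrorMSE <- function(original, mirrored) {
  A <- pixels(original); B <- pixels(mirrored)
  if (!all(dim(A) == dim(B))) stop("mirrorMSE: dimension mismatch")
  mean((A - B)^2)
}

#' Approximation subband of a separable 2D discrete wavelet transform
#'
#' Computes the level-\code{level} approximation (low-pass) subband of an
#' orthogonal 2D DWT. The default wavelet is Haar (db1), whose single-level
#' approximation of a constant image \code{c} is the constant \code{2c}
#' (low-pass gain sqrt(2) per dimension). Odd-sized inputs are extended by
#' replicating the last row/column before each level.
#'
#' @param map an \linkS4class{AsymmetryMap}, \linkS4class{GrayImage} or
#'   numeric matrix.
#' @param wavelet wavelet name; \code{"haar"} and its alias \code{"db1"} are
#'   supported.
#' @param level decomposition depth (>= 1).
#' @return Numeric matrix of approximation coefficients.
#' @export
dwtApprox <- function(map, wavelet = "haar", level = 1) {
  M <- if (is.matrix(map)) map else pixels(map)
  if (!(tolower(wavelet) %in% c("haar", "db1"))) {
    stop("unsupported wavelet: ", wavelet, " (supported: haar/db1)")
  }
  if (level < 1) stop("level must be >= 1")
  for (l in seq_len(level)) {
    if (nrow(M) < 2 || ncol(M) < 2) {
      stop("image smaller than wavelet filter support at level ", l)
    }
    M <- .haar_dwt2(M)$LL
  }
  M
}

# One level of the 2D Haar transform; returns all four subbands.
# Filters (1,1)/sqrt(2) and (1,-1)/sqrt(2) on non-overlapping pairs.
.haar_dwt2 <- function(M) {
  if (nrow(M) %% 2 == 1) M <- rbind(M, M[nrow(M), ])
  if (ncol(M) %% 2 == 1) M <- cbind(M, M[, ncol(M)])
  ro <- M[seq(1, nrow(M), 2), , drop = FALSE]
  re <- M[seq(2, nrow(M), 2), , drop = FALSE]
  L_r <- (ro + re) / sqrt(2)   # row-direction low-pass
  H_r <- (ro - re) / sqrt(2)
  co <- function(X) X[, seq(1, ncol(X), 2), drop = FALSE]
  ce <- function(X) X[, seq(2, ncol(X), 2), drop = FALSE]
  list(LL = (co(L_r) + ce(L_r)) / sqrt(2),
       LH = (co(L_r) - ce(L_r)) / sqrt(2),
       HL = (co(H_r) + ce(H_r)) / sqrt(2),
       HH = (co(H_r) - ce(H_r)) / sqrt(2))
}

# population moments
.pop_var <- function(x) mean((x - mean(x))^2)

# min-max rescale to [0, span]; constant vectors map to 0
.unit_scale <- function(x, span = 1) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * span else x * 0
}

# Shannon entropy (bits) of a 256-bin histogram of values scaled to [0,255]
.hist_entropy <- function(x) {
  bins <- pmin(floor(.unit_scale(x, 255)), 255)
  p <- tabulate(bins + 1L, nbins = 256L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Normalized symmetric GLCM at offset (0,1) over 256 gray levels, and its
# inverse difference moment sum P(i,j)/(1+(i-j)^2). Implemented via the
# distribution of level differences |i-j|, which is all IDM needs.
.glcm_idm <- function(x, normalized = TRUE) {
  Q <- matrix(pmin(round(.unit_scale(x, 255)), 255), nrow(x), ncol(x))
  a <- Q[, -ncol(Q), drop = FALSE]
  b <- Q[, -1, drop = FALSE]
  d <- abs(a - b)                       # symmetric pairs share |i-j|
  w <- sum(2 / (1 + d^2))               # both (i,j) and (j,i) entries
  if (normalized) w / (2 * length(d)) else w
}

#' Ten-statistic feature vector of an asymmetry map
#'
#' Computes the ordered feature vector (MSE, Mean, Std, Entropy, RMS,
#' Variance, Smoothness, Kurtosis, Skewness, IDM). MSE comes from
#' \code{\link{mirrorMSE}} of the aligned slice against its vertical mirror;
#' all other statistics are computed on the DWT approximation subband of the
#' map: raw population moments (Mean, Std, Variance, RMS, Kurtosis,
#' Skewness), Shannon entropy in bits of the 256-bin histogram of the
#' subband rescaled to \[0, 255\], smoothness \code{1 - 1/(1 + var)} with
#' the variance of subband values rescaled to \[0, 1\], and the inverse
#' difference moment of a normalized symmetric 256-level co-occurrence
#' matrix at offset (0, 1).
#'
#' For a degenerate all-constant subband, kurtosis and skewness are
#' undefined and are returned as 0 with a warning; entropy and smoothness
#' are 0 and IDM is 1 by continuity of their definitions.
#'
#' @param map an \linkS4class{AsymmetryMap}.
#' @param original the aligned \linkS4class{GrayImage} the map came from
#'   (used for MSE only).
#' @param wavelet,level passed to \code{\link{dwtApprox}}.
#' @param idm_normalized if FALSE, report the IDM of the unnormalized
#'   co-occurrence counts (a compatibility option; the default normalized
#'   form is scale-invariant and bounded in (0, 1\]).
#' @return Named numeric vector of length 10 in the fixed order above.
#' @export
statFeatures <- function(map, original, wavelet = "haar", level = 1,
                         idm_normalized = TRUE) {
  stopifnot(is(map, "AsymmetryMap"), is(original, "GrayImage"))
  A <- dwtApprox(map, wavelet = wavelet, level = level)
  x <- as.vector(A)
  mu <- mean(x)
  v <- .pop_var(x)
  s <- sqrt(v)
  if (v == 0) {
    warning("degenerate (constant) subband: kurtosis/skewness undefined, ",
            "reported as 0")
    kurt <- 0; skew <- 0
  } else {
    kurt <- mean((x - mu)^4) / v^2
    skew <- mean((x - mu)^3) / v^1.5
  }
  out <- c(
    MSE = mirrorMSE(original, mirrorVertical(original)),
    Mean = mu,
    Std = s,
    Entropy = .hist_entropy(x),
    RMS = sqrt(mean(x^2)),
    Variance = v,
    Smoothness = 1 - 1 / (1 + .pop_var(.unit_scale(x))),
    Kurtosis = kurt,
    Skewness = skew,
    IDM = .glcm_idm(A, normalized = idm_normalized)
  )
  out[STAT_FEATURE_NAMES]
}

#' Assemble a feature table for a set of labelled maps
#'
#' @param maps list of \linkS4class{AsymmetryMap}s.
#' @param originals list of the corresponding aligned
#'   \linkS4class{GrayImage}s.
#' @param labels character vector of class labels (NC/EMCI/AD).
#' @param ... passed to \code{\link{statFeatures}}.
#' @return data.frame with columns source_id, label and the 10 named
#'   statistics, one row per map.
#' @export
featureTable <- function(maps, originals, labels, ...) {
  stopifnot(length(maps) == length(originals),
            length(maps) == length(labels))
  rows <- mapply(function(m, o) statFeatures(m, o, ...),
                 maps, originals, SIMPLIFY = FALSE)
  df <- as.data.frame(do.call(rbind, rows))
  data.frame(
    source_id = vapply(maps, function(m) m@parentId, character(1)),
    label = as.character(labels), df,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Min-max normalize feature columns across a dataset
#'
#' Rescales each feature column to \[0, 1\] over the supplied records
#' (constant columns map to 0). The per-column minima and maxima are stored
#' in the \code{"ranges"} attribute so the scaling is invertible.
#'
#' @param records data.frame from \code{\link{featureTable}} (non-numeric
#'   columns are passed through untouched).
#' @return data.frame of the same shape with numeric columns in \[0, 1\].
#' @export
normalizeFeatures <- function(records) {
  if (nrow(records) < 2) stop("normalizeFeatures: need >= 2 records")
  num <- vapply(records, is.numeric, logical(1))
  ranges <- lapply(records[num], range)
  records[num] <- lapply(records[num], function(x) {
    rng <- range(x)
    if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  })
  attr(records, "ranges") <- ranges
  records
}

#' Per-class means of each feature
#'
#' @param records labelled feature data.frame (typically normalized).
#' @return data.frame with one row per class and one column per feature.
#' @export
classFeatureMeans <- function(records) {
  if (nrow(records) == 0) stop("classFeatureMeans: empty input")
  num <- vapply(records, is.numeric, logical(1))
  agg <- aggregate(records[num], by = list(label = records$label), mean)
  agg
}

#' Pareto breakdown of total MSE by class
#'
#' Sums the mirror-MSE feature within each class, orders classes by
#' descending total, and reports each class's cumulative percentage of the
#' grand total.
#'
#' @param records labelled feature data.frame with an \code{MSE} column.
#' @return data.frame with columns label, total_mse, cumulative_pct, in
#'   descending order of total_mse.
#' @export
msePareto <- function(records) {
  if (nrow(records) == 0) stop("msePareto: empty input")
  totals <- tapply(records$MSE, records$label, sum)
  totals <- sort(totals, decreasing = TRUE)
  data.frame(
    label = names(totals),
    total_mse = as.numeric(totals),
    cumulative_pct = 100 * cumsum(as.numeric(totals)) / sum(totals),
    row.names = NULL, stringsAsFactors = FALSE)
}
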