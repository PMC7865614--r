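# Shared fixtures: tiny deterministic images and phantom shortcuts.

# GrayImage from a matrix literal
gi <- function(M) GrayImage(M)

# random integer-valued image in [0, 255]
random_image <- function(H, W, seed) {
  withr::with_seed(seed, GrayImage(matrix(sample(0:255, H * W, replace = TRUE), H, W)))
}

# a clean (aligned-frame, noise-free) phantom
clean_phantom <- function(label = "NC", seed = 1, ...) {
  generatePhantom(label = label, noise_sigma = 0, seed = seed, ...)
}

# compact-support radius of the truncated Gaussian lesion profile
lesion_footprint_radius <- function(lesion_radius) {
  sqrt(-2 * log(1e-6)) * lesion_radius / 2
}

# independent bilinear interpolation oracle at a single 0-based point
# (value 0 outside the raster)
oracle_bilinear <- function(M, r, c) {
  H <- nrow(M); W <- ncol(M)
  r0 <- floor(r); c0 <- floor(c)
  acc <- 0
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (1 - abs(r - ri)) * (1 - abs(c - ci))
    v <- if (ri >= 0 && ri < H && ci >= 0 && ci < W) M[ri + 1, ci + 1] else 0
    acc <- acc + w * v
  }
  acc
}

# brute-force saturating two-way mirror subtraction on an integer matrix
oracle_saturating_map <- function(M) {
  R <- M[, rev(seq_len(ncol(M)))]
  D <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    D[i, j] <- max(M[i, j] - R[i, j], 0) + max(R[i, j] - M[i, j], 0)
  }
  D
}

# brute-force AUC by pair counting (ties count 1/2)
oracle_auc_paircount <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}
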