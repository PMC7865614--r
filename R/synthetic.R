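# Synthetic brain-slice phantom generator.
#
# Phantoms emulate the geometry a hemispheric-asymmetry pipeline sees in a
# 2D T1 slice: a bright elliptical "skull" ring separated from an inner
# tissue ellipse by a dark gap, smooth tissue texture made mirror-symmetric
# by construction, a dark medial ventricle pair, and a controlled number of
# unilateral Gaussian "lesions" that are the sole source of ground-truth
# asymmetry. Pose perturbation (rotation then translation) and additive
# Gaussian noise are applied after rendering, so alignment has to cope with
# noisy mirror residuals. Everything is deterministic given the seed.
#
# Default per-class lesion amplitudes follow the clinical ordering in which
# early mild cognitive impairment presents with *reduced* asymmetry and
# Alzheimer's disease with markedly increased asymmetry:
# EMCI (2) < NC (6) < AD (14) intensity units.

.CLASS_AMPLITUDES <- c(EMCI = 2, NC = 6, AD = 14)

#' Default per-class asymmetry amplitudes
#'
#' @return Named numeric vector of lesion amplitudes (intensity units) for
#'   EMCI, NC and AD phantom classes.
#' @export
classAmplitudes <- function() .CLASS_AMPLITUDES

#' Generate one synthetic brain-slice phantom
#'
#' @param label class label, one of "NC", "EMCI", "AD" (free-form labels
#'   are allowed for custom experiments).
#' @param asymmetry_amplitude peak lesion intensity added to one hemisphere
#'   (default: the class default amplitude).
#' @param n_lesions number of unilateral Gaussian lesions.
#' @param lesion_radius nominal lesion radius in pixels (Gaussian sigma is
#'   radius/2; the profile is truncated where it falls below 1e-6, giving
#'   a compact footprint of radius about 5.26 sigma).
#' @param rotation_deg in-plane rotation applied after rendering (degrees,
#'   CCW positive).
#' @param shift length-2 (rows, cols) translation applied after rotation.
#' @param noise_sigma sd of additive Gaussian noise (intensity units),
#'   added last.
#' @param skull render the bright skull ring.
#' @param size image edge length (default 256).
#' @param seed integer RNG seed; identical specs+seeds render bit-identical
#'   phantoms.
#' @return A \linkS4class{PhantomBundle}.
#' @export
generatePhantom <- function(label = "NC",
                            asymmetry_amplitude = NULL,
                            n_lesions = 3, lesion_radius = 6,
                            rotation_deg = 0, shift = c(0, 0),
                            noise_sigma = 2, skull = TRUE,
                            size = 256, seed = 1) {
  if (is.null(asymmetry_amplitude)) {
    asymmetry_amplitude <-
      if (label %in% names(.CLASS_AMPLITUDES)) .CLASS_AMPLITUDES[[label]]
      else stop("no default amplitude for label '", label,
                "'; supply asymmetry_amplitude")
  }
  stopifnot(asymmetry_amplitude >= 0, n_lesions >= 0, noise_sigma >= 0)
  spec <- list(label = label, asymmetry_amplitude = asymmetry_amplitude,
               n_lesions = n_lesions, lesion_radius = lesion_radius,
               rotation_deg = rotation_deg, shift = shift,
               noise_sigma = noise_sigma, skull = skull, size = size,
               seed = as.integer(seed))
  withr::with_seed(as.integer(seed), {
    H <- size; W <- size
    cr <- (H - 1) / 2; cc <- (W - 1) / 2
    g <- .coord_grid(H, W)
    R <- matrix(g$r, H, W); C <- matrix(g$c, H, W)
    # tissue ellipse (semi-axes scale with image size)
    ar <- 0.39 * H; ac <- 0.31 * W
    e <- ((R - cr) / ar)^2 + ((C - cc) / ac)^2
    tissue <- e <= 1
    M <- matrix(0, H, W)
    # smooth symmetric texture: base level, radial falloff, mirrored bumps
    rows <- seq_len(H) - 1; cols <- seq_len(W) - 1
    gauss2d <- function(r0, c0, s) {  # separable outer product,
      g <- exp(-(rows - r0)^2 / (2 * s^2)) %o%
        exp(-(cols - c0)^2 / (2 * s^2))
      g[g < 1e-6] <- 0  # compact support (radius ~5.26 sigma)
      g
    }
    tex <- 130 - 30 * e
    for (b in seq_len(8)) {
      br <- stats::runif(1, cr - 0.7 * ar, cr + 0.7 * ar)
      bc <- stats::runif(1, cc - 0.7 * ac, cc + 0.7 * ac)
      bs <- stats::runif(1, 10, 30)
      ba <- stats::runif(1, -25, 25)
      tex <- tex + ba * gauss2d(br, bc, bs)
    }
    tex <- (tex + .mirror_mat(tex)) / 2      # exact mirror symmetry
    M[tissue] <- tex[tissue]
    # medial ventricle pair (mirror-symmetric dark ellipses)
    for (vc in c(cc - 0.07 * W, cc + 0.07 * W)) {
      ev <- ((R - cr) / (0.11 * H))^2 + ((C - vc) / (0.03 * W))^2
      M[ev <= 1] <- M[ev <= 1] - 50
    }
    # skull ring, separated from tissue by a dark gap
    if (skull) {
      e_out <- ((R - cr) / (ar + 0.045 * H))^2 + ((C - cc) / (ac + 0.045 * W))^2
      e_in <- ((R - cr) / (ar + 0.02 * H))^2 + ((C - cc) / (ac + 0.02 * W))^2
      M[e_out <= 1 & e_in > 1] <- 240
    }
    # unilateral lesions: entirely inside tissue, clear of the midline so
    # their footprint cannot overlap its own mirror image
    lesions <- data.frame(row = numeric(0), col = numeric(0),
                          radius = numeric(0), amplitude = numeric(0))
    for (l in seq_len(n_lesions)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        lr <- stats::runif(1, cr - 0.8 * ar, cr + 0.8 * ar)
        lc <- stats::runif(1, cc - 0.8 * ac, cc - 2 * lesion_radius)
        e_l <- ((lr - cr) / ar)^2 + ((lc - cc) / ac)^2
        if (e_l <= 0.7) { placed <- TRUE; break }
      }
      if (!placed) stop("generatePhantom: could not place lesion ", l,
                        " inside tissue after 100 tries")
      sig <- lesion_radius / 2
      M <- M + asymmetry_amplitude * gauss2d(lr, lc, sig)
      lesions <- rbind(lesions, data.frame(
        row = lr, col = lc, radius = lesion_radius,
        amplitude = asymmetry_amplitude))
    }
    M <- pmin(pmax(M, 0), 255)
    # pose perturbation: rotation about the center, then translation
    if (rotation_deg != 0) M <- .rotate_mat(M, rotation_deg)
    if (any(shift != 0)) M <- .translate_mat(M, shift)
    if (noise_sigma > 0) {
      M <- M + stats::rnorm(length(M), sd = noise_sigma)
      M <- pmin(pmax(M, 0), 255)
    }
    img <- GrayImage(M, sourceId = sprintf("phantom_%s_seed%d", label, seed))
    new("PhantomBundle",
        image = img,
        truthMaskTissue = new("BinaryMask", pixels = tissue * 1,
                              thresholdUsed = NA_real_),
        truthLesions = lesions,
        truthPose = list(rotation_deg = rotation_deg, shift = shift),
        spec = spec)
  })
}

#' Generate a balanced labelled phantom cohort
#'
#' Renders \code{n_per_class} phantoms for each class with per-image seeds
#' derived deterministically from the master seed. By default phantoms are
#' rendered in the aligned frame (no pose perturbation); set
#' \code{pose_max_deg}/\code{pose_max_shift} to randomize pose per image,
#' e.g. for alignment benchmarks.
#'
#' @param n_per_class phantoms per class (>= 1).
#' @param class_params named list mapping class label to a list of
#'   \code{\link{generatePhantom}} overrides (default: the three dementia
#'   classes at their default amplitudes).
#' @param seed master seed.
#' @param pose_max_deg,pose_max_shift half-ranges of the uniform random
#'   pose perturbation (degrees / pixels); both default to 0.
#' @param ... further arguments passed to every \code{generatePhantom}
#'   call (e.g. \code{noise_sigma}, \code{size}).
#' @return List of \linkS4class{PhantomBundle}s, classes interleaved.
#' @export
generateCohort <- function(n_per_class, class_params = NULL, seed = 1,
                           pose_max_deg = 0, pose_max_shift = 0, ...) {
  stopifnot(n_per_class >= 1)
  if (is.null(class_params)) {
    class_params <- lapply(names(.CLASS_AMPLITUDES), function(l) list())
    names(class_params) <- names(.CLASS_AMPLITUDES)
  }
  labels <- names(class_params)
  n_total <- n_per_class * length(labels)
  draws <- withr::with_seed(as.integer(seed), {
    list(seeds = sample.int(.Machine$integer.max - 1, n_total),
         angles = stats::runif(n_total, -pose_max_deg, pose_max_deg),
         shifts = matrix(stats::runif(2 * n_total, -pose_max_shift,
                                      pose_max_shift), ncol = 2))
  })
  common <- list(...)
  bundles <- vector("list", n_total)
  i <- 0
  for (rep_ in seq_len(n_per_class)) {
    for (lab in labels) {
      i <- i + 1
      args <- c(list(label = lab, seed = draws$seeds[i],
                     rotation_deg = if (pose_max_deg > 0) draws$angles[i] else 0,
                     shift = if (pose_max_shift > 0) draws$shifts[i, ] else c(0, 0)),
                class_params[[lab]], common)
      bundles[[i]] <- do.call(generatePhantom, args)
    }
  }
  bundles
}
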