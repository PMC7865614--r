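# Symmetry-axis detection and asymmetry-map extraction.

test_that("binarize thresholds correctly, including Otsu auto mode", {
  expect_true(all(pixels(binarize(gi(matrix(200, 5, 5)), 100)) == 1))
  # bimodal image: auto threshold separates the two levels exactly
  M <- matrix(0, 10, 10); M[, 6:10] <- 255
  mask <- binarize(gi(M), "auto")
  expect_equal(pixels(mask), (M > 0) * 1)
  # ramp 0..255 with threshold 127: pixels 128..255 are set
  ramp <- gi(matrix(0:255, 16, 16))
  expect_equal(sum(pixels(binarize(ramp, 127))), sum(0:255 > 127))
  expect_error(binarize(gi(matrix(0, 4, 4))), "empty image")
})

test_that("maskCentroid computes unweighted and weighted centroids", {
  M <- matrix(0, 30, 30); M[11, 21] <- 1    # 0-based (10, 20)
  mask <- binarize(gi(M * 255), 1)
  expect_equal(maskCentroid(mask), c(10, 20))
  # centered disk in a 256x256 frame
  g <- expand.grid(r = 0:255, c = 0:255)
  disk <- matrix(as.numeric((g$r - 127.5)^2 + (g$c - 127.5)^2 <= 50^2),
                 256, 256)
  expect_equal(maskCentroid(binarize(gi(disk * 255), 1)), c(127.5, 127.5))
  # weights 1 and 3 at (0,0) and (0,10): weighted mean col 7.5
  W <- matrix(0, 5, 15); W[1, 1] <- 1; W[1, 11] <- 3
  mask2 <- binarize(gi(W * 50), 1)
  expect_equal(maskCentroid(mask2, weights = gi(W)), c(0, 7.5))
  expect_error(maskCentroid(binarize(gi(matrix(1, 2, 2)), 200)), "empty")
})

test_that("translateToCenter shifts exactly and conserves mass", {
  # centroid already central: unchanged
  img <- random_image(64, 64, seed = 3)
  out <- translateToCenter(img, c(31.5, 31.5))
  expect_equal(pixels(out), pixels(img))
  # integer shift is a pure permutation of a disk
  M <- matrix(0, 64, 64); M[20:30, 20:30] <- 77
  sh <- translateToCenter(gi(M), c(25, 25))   # center (31.5,31.5): +6.5 -> subpixel
  M2 <- matrix(0, 64, 64); M2[24:34, 24:34] <- 77
  int_sh <- translateToCenter(gi(M), c(27.5, 27.5))  # integer shift +4
  expect_equal(pixels(int_sh), M2)
  # subpixel shift of a single bright pixel: bilinear weights sum to value
  P <- matrix(0, 256, 256); P[101, 101] <- 200  # 0-based (100,100)
  moved <- pixels(translateToCenter(gi(P), c(100, 100)))
  expect_equal(sum(moved), 200, tolerance = 1e-9)
  nz <- which(moved > 0, arr.ind = TRUE)
  expect_true(all(abs(nz - 128.5) <= 1))  # mass lands around (127.5, 127.5)
  expect_error(translateToCenter(gi(P), c(-500, 0)), "exceeds image size")
})

test_that("mirrorVertical reverses columns and is an involution", {
  expect_equal(mirrorVertical(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(c(2, 4, 1, 3), 2, 2))
  img <- random_image(15, 22, seed = 8)
  expect_equal(pixels(mirrorVertical(mirrorVertical(img))), pixels(img))
  sym <- clean_phantom("NC", asymmetry_amplitude = 0, n_lesions = 0,
                       seed = 2)
  expect_equal(pixels(mirrorVertical(sym@image)), pixels(sym@image))
})

test_that("symmetryObjective is the mean squared mirror difference on the union support", {
  sym <- clean_phantom("NC", asymmetry_amplitude = 0, n_lesions = 0, seed = 4)
  expect_equal(symmetryObjective(sym@image), 0)
  expect_equal(symmetryObjective(gi(matrix(100, 6, 6))), 0)
  # closed form on a 4x4 toy: left half zeroed
  withr::with_seed(13, M <- matrix(sample(50:255, 16), 4, 4))
  Mz <- M; Mz[, 1:2] <- 0
  # support is all 16 pixels (each nonzero on one side); each right-half
  # value x contributes x^2 twice (at its own and its mirrored position)
  expected <- 2 * sum(Mz[, 3:4]^2) / 16
  expect_equal(symmetryObjective(gi(Mz)), expected, tolerance = 1e-12)
  expect_error(symmetryObjective(gi(matrix(0, 4, 4))), "blank")
})

test_that("asymmetryMap equals the brute-force saturating oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      M <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
      expect_equal(pixels(asymmetryMap(gi(M))), oracle_saturating_map(M))
    }
  })
  # symmetric input: identically zero
  sym <- clean_phantom("EMCI", asymmetry_amplitude = 0, n_lesions = 0,
                       seed = 5)
  expect_true(all(pixels(asymmetryMap(sym@image)) == 0))
  # single pixel appears at its column and the mirrored column
  M <- matrix(0, 8, 8); M[3, 2] <- 99
  D <- pixels(asymmetryMap(gi(M)))
  expect_equal(D[3, 2], 99)
  expect_equal(D[3, 7], 99)
  expect_equal(sum(D), 2 * 99)
})

test_that("asymmetryMap is invariant under mirroring of its input", {
  for (s in 1:5) {
    img <- random_image(12, 12, seed = 100 + s)
    expect_equal(pixels(asymmetryMap(mirrorVertical(img))),
                 pixels(asymmetryMap(img)))
  }
})

test_that("findSymmetryRotation recovers rotations and breaks ties at zero", {
  sym <- clean_phantom("NC", asymmetry_amplitude = 0, n_lesions = 0, seed = 6)
  expect_equal(findSymmetryRotation(sym@image)$angle, 0)
  # rotated symmetric phantom: optimum within one grid step of -5
  rot <- rotateImage(sym@image, 5)
  res <- findSymmetryRotation(rot)
  expect_lte(abs(res$angle + 5), 0.5)
  # grid optimality: the returned angle beats every other grid angle
  angles <- seq(-15, 15, by = 2.5)
  scores <- vapply(angles, function(a)
    symmetryObjective(rotateImage(rot, a)), numeric(1))
  expect_lte(res$score, min(scores) + 1e-9)
  # circularly symmetric disk: all angles tie; tie-break picks 0
  g <- expand.grid(r = 0:127, c = 0:127)
  disk <- matrix(as.numeric((g$r - 63.5)^2 + (g$c - 63.5)^2 <= 40^2) * 180,
                 128, 128)
  expect_equal(findSymmetryRotation(gi(disk), 5, 1)$angle, 0)
})

test_that("alignAndExtract recovers pose and preserves lesion contrast", {
  # symmetric centered phantom: no shift, no rotation, all-zero map
  sym <- clean_phantom("NC", asymmetry_amplitude = 0, n_lesions = 0, seed = 7)
  res <- alignAndExtract(sym@image)
  expect_equal(angleDeg(res$alignment), 0)
  expect_equal(shiftRC(res$alignment), c(0, 0))
  expect_true(all(pixels(res$map) == 0))
  # posed phantom: pose recovered within 1 px and one grid step
  b <- generatePhantom("AD", rotation_deg = 4, shift = c(8, -5),
                       noise_sigma = 2, seed = 77)
  res <- alignAndExtract(skullStrip(b@image, c(30, 200)))
  expect_lte(max(abs(shiftRC(res$alignment) - c(-8, 5))), 1)
  expect_lte(abs(angleDeg(res$alignment) + 4), 0.5)
  # lesion contrast survives alignment up to interpolation tolerance
  amp <- 20
  b2 <- generatePhantom("AD", asymmetry_amplitude = amp, n_lesions = 1,
                        rotation_deg = 3, shift = c(4, 6), noise_sigma = 0,
                        seed = 78)
  res2 <- alignAndExtract(skullStrip(b2@image, c(30, 200)))
  expect_gte(max(pixels(res2$map)), amp - 2)
  # stage errors are labelled with the failing stage
  expect_error(alignAndExtract(gi(matrix(0, 16, 16))), "binarize")
})
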