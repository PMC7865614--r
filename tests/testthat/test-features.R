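# Statistical texture features, wavelet subband, normalization, Pareto.

test_that("mirrorMSE matches elementwise brute force", {
  a <- gi(matrix(100, 4, 4))
  expect_equal(mirrorMSE(a, a), 0)
  expect_equal(mirrorMSE(gi(matrix(10, 3, 3)), gi(matrix(20, 3, 3))), 100)
  A <- random_image(7, 9, seed = 1); B <- random_image(7, 9, seed = 2)
  acc <- 0
  for (i in 1:7) for (j in 1:9) acc <- acc + (pixels(A)[i, j] - pixels(B)[i, j])^2
  expect_equal(mirrorMSE(A, B), acc / 63, tolerance = 1e-9)
  expect_error(mirrorMSE(A, random_image(7, 8, seed = 3)), "dimension")
})

test_that("Haar approximation subband has low-pass gain 2 and conserves energy", {
  expect_equal(dwtApprox(matrix(7, 2, 2)), matrix(14, 1, 1))
  expect_equal(dwtApprox(matrix(3, 8, 8)), matrix(6, 4, 4))
  expect_equal(dwtApprox(matrix(3, 8, 8), level = 2), matrix(12, 2, 2))
  # orthogonality: all four level-1 subbands conserve energy
  withr::with_seed(9, M <- matrix(runif(64, 0, 255), 8, 8))
  sb <- hemiAsym:::.haar_dwt2(M)
  expect_equal(sum(unlist(sb)^2), sum(M^2), tolerance = 1e-6 * sum(M^2))
  expect_error(dwtApprox(matrix(1, 1, 4)), "filter support")
  expect_error(dwtApprox(matrix(1, 4, 4), wavelet = "sym4"), "unsupported")
})

test_that("statFeatures keeps the fixed order and its internal identities", {
  b <- clean_phantom("AD", seed = 12)
  res <- alignAndExtract(skullStrip(b@image, c(30, 200)))
  f <- statFeatures(res$map, res$aligned)
  expect_identical(names(f), c("MSE", "Mean", "Std", "Entropy", "RMS",
                               "Variance", "Smoothness", "Kurtosis",
                               "Skewness", "IDM"))
  expect_equal(f[["Variance"]], f[["Std"]]^2, tolerance = 1e-9)
  expect_equal(f[["RMS"]]^2, f[["Mean"]]^2 + f[["Variance"]],
               tolerance = 1e-9 * f[["RMS"]]^2)
  expect_gte(f[["Entropy"]], 0); expect_lte(f[["Entropy"]], 8)
  expect_gt(f[["IDM"]], 0); expect_lte(f[["IDM"]], 1)
  expect_gte(f[["Smoothness"]], 0); expect_lt(f[["Smoothness"]], 1)
  expect_equal(f[["MSE"]], mirrorMSE(res$aligned, mirrorVertical(res$aligned)))
})

test_that("degenerate all-zero map follows the defined contract", {
  orig <- random_image(16, 16, seed = 4)
  zmap <- AsymmetryMap(matrix(0, 16, 16))
  expect_warning(f <- statFeatures(zmap, orig), "undefined")
  expect_equal(unname(f[c("Mean", "Std", "Entropy", "RMS", "Variance",
                          "Smoothness", "Kurtosis", "Skewness")]),
               rep(0, 8))
  expect_equal(f[["IDM"]], 1)
  expect_equal(f[["MSE"]], mirrorMSE(orig, mirrorVertical(orig)))
})

test_that("subband entropy matches a hand-computed histogram", {
  # half-zero, half-255 map: subband is two-valued; entropy of the
  # 256-bin histogram equals 1 bit
  M <- matrix(0, 16, 16); M[, 9:16] <- 255
  A <- dwtApprox(M)
  x <- hemiAsym:::.unit_scale(as.vector(A), 255)
  counts <- table(pmin(floor(x), 255))
  p <- as.numeric(counts) / length(x)
  expect_equal(hemiAsym:::.hist_entropy(as.vector(A)), -sum(p * log2(p)))
  expect_equal(hemiAsym:::.hist_entropy(as.vector(A)), 1)
})

test_that("all ten statistics are invariant under mirroring of the map", {
  b <- clean_phantom("AD", seed = 15)
  res <- alignAndExtract(skullStrip(b@image, c(30, 200)))
  f1 <- statFeatures(res$map, res$aligned)
  f2 <- statFeatures(mirrorVertical(res$map), mirrorVertical(res$aligned))
  expect_equal(f2, f1, tolerance = 1e-12)
})

test_that("mirror MSE increases strictly with injected lesion amplitude", {
  mses <- vapply(c(2, 6, 14, 30), function(a) {
    b <- generatePhantom("NC", asymmetry_amplitude = a, n_lesions = 2,
                         noise_sigma = 0, seed = 50)
    mirrorMSE(b@image, mirrorVertical(b@image))
  }, numeric(1))
  expect_true(all(diff(mses) > 0))
})

test_that("normalizeFeatures min-max scales columns and round-trips", {
  df <- data.frame(label = c("a", "b", "c"), F1 = c(2, 4, 6), F2 = c(5, 5, 5))
  out <- normalizeFeatures(df)
  expect_equal(out$F1, c(0, 0.5, 1))
  expect_equal(out$F2, c(0, 0, 0))
  rng <- attr(out, "ranges")
  back <- out$F1 * (rng$F1[2] - rng$F1[1]) + rng$F1[1]
  expect_equal(back, df$F1, tolerance = 1e-12)
  expect_error(normalizeFeatures(df[1, ]), ">= 2")
})

test_that("classFeatureMeans reproduces group-by means", {
  df <- data.frame(label = c("NC", "NC", "AD"), F1 = c(1, 3, 10))
  m <- classFeatureMeans(df)
  expect_equal(m$F1[m$label == "NC"], 2)
  expect_equal(m$F1[m$label == "AD"], 10)
  withr::with_seed(3, {
    big <- data.frame(label = sample(c("NC", "EMCI", "AD"), 60, TRUE),
                      F1 = rnorm(60), F2 = rnorm(60))
  })
  m2 <- classFeatureMeans(big)
  for (cl in unique(big$label)) {
    expect_equal(m2$F1[m2$label == cl], mean(big$F1[big$label == cl]))
  }
  expect_error(classFeatureMeans(big[0, ]), "empty")
})

test_that("msePareto orders class totals with cumulative percentages", {
  df <- data.frame(label = c("AD", "NC", "EMCI"), MSE = c(60, 30, 10))
  p <- msePareto(df)
  expect_equal(p$label, c("AD", "NC", "EMCI"))
  expect_equal(p$cumulative_pct, c(60, 90, 100))
  single <- msePareto(data.frame(label = "NC", MSE = 5))
  expect_equal(single$cumulative_pct, 100)
  expect_error(msePareto(df[0, ]), "empty")
})
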