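# Model construction, ROC/AUC, cross-validation harness.

sep_data <- function(n = 100, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * 4 / 2), n / 2, 4),
               matrix(rnorm(n * 4 / 2, mean = gap), n / 2, 4))
    list(X = X, y = rep(c("NC", "AD"), each = n / 2))
  })
}

test_that("makeModel configures the eight specifications and rejects others", {
  m <- makeModel("C-SVM")
  expect_equal(m$hyperparameters$degree, 3)
  expect_equal(m$hyperparameters$cost, 1)
  expect_identical(m$hyperparameters$kernel_scale, "auto")
  expect_true(m$standardize)
  expect_equal(makeModel("MG-SVM")$hyperparameters$kernel_scale, 32)
  expect_equal(makeModel("Fine-KNN")$hyperparameters$k, 1)
  expect_equal(makeModel("Cos-KNN")$hyperparameters$k, 10)
  expect_false(makeModel("NB")$standardize)
  expect_error(makeModel("XGB"), "valid models")
  expect_error(makeModel("C-SVM", bandwidth = 2), "unknown hyperparameter")
})

test_that("rocAuc sweeps thresholds and equals the pair-counting statistic", {
  # perfect separation
  r <- rocAuc(c(1, 2, 3, 10, 11, 12), rep(c("n", "p"), each = 3))
  expect_equal(r$auc, 1)
  # all-tied scores give 0.5
  expect_equal(rocAuc(rep(1, 10), rep(c("n", "p"), 5))$auc, 0.5)
  # random instances with ties: trapezoid == U/(n1 n2)
  withr::with_seed(31, {
    for (i in 1:20) {
      sc <- sample(1:8, 20, replace = TRUE)  # heavy ties
      y <- sample(rep(c("n", "p"), each = 10))
      expect_equal(rocAuc(sc, y, positive = "p")$auc,
                   oracle_auc_paircount(sc, y == "p"), tolerance = 1e-12)
    }
  })
  # invariance under strictly monotone transforms
  withr::with_seed(5, {
    sc <- rnorm(30); y <- sample(rep(c("n", "p"), 15))
  })
  expect_equal(rocAuc(exp(2 * sc) + 3, y)$auc, rocAuc(sc, y)$auc)
  expect_error(rocAuc(1:5, rep("p", 5)), "both classes")
})

test_that("rocAuc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    sc <- c(rnorm(25), rnorm(25, 1))
    y <- rep(c("n", "p"), each = 25)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(rocAuc(sc, y, positive = "p")$auc, ref, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and respects the protocol", {
  d <- sep_data(60, gap = 8, seed = 2)
  r1 <- crossValidate(d$X, d$y, "LD", runs = 3, folds = 5, seed = 9,
                      positive = "AD")
  r2 <- crossValidate(d$X, d$y, "LD", runs = 3, folds = 5, seed = 9,
                      positive = "AD")
  expect_identical(r1@perFold, r2@perFold)
  expect_identical(r1@auc, r2@auc)
  expect_equal(nrow(r1@perFold), 15)
  # every fold satisfies the confusion identities
  with(r1@perFold, {
    expect_true(all(TP + FP + TN + FN == 12))  # 60 samples / 5 folds
    expect_true(all(TP + FN == 6))             # stratified: 6 positives
  })
  expect_error(crossValidate(d$X, rep("AD", 60), "LD"), "two classes")
  expect_error(crossValidate(d$X[1:10, ], d$y[c(1:5, 31:35)], "LD",
                             folds = 10), "folds")
})

test_that("separable classes reach 100% and permuted labels stay at chance", {
  d <- sep_data(200, gap = 10, seed = 3)
  r <- crossValidate(d$X, d$y, "C-SVM", runs = 2, folds = 10, seed = 4,
                     positive = "AD")
  expect_equal(r@accuracy, 100)
  expect_equal(r@auc, 1)
  # permutation null: the accuracy of one permuted dataset is itself a
  # random quantity with a few percent of dataset-to-dataset spread, so
  # average over independent permutation draws before asserting the 99%
  # binomial band around 50%
  null_accs <- vapply(1:6, function(i) {
    withr::with_seed(10 + i, {
      Xn <- matrix(rnorm(200 * 4), 200, 4)
      yp <- sample(d$y)
    })
    crossValidate(Xn, yp, "LD", runs = 2, folds = 10, seed = i,
                  positive = "AD")@accuracy
  }, numeric(1))
  expect_gt(mean(null_accs), 40)
  expect_lt(mean(null_accs), 60)
})

test_that("all eight models train, score and beat chance when separable", {
  d <- sep_data(80, gap = 6, seed = 6)
  for (m in c("NB", "LD", "L-SVM", "Q-SVM", "C-SVM", "MG-SVM",
              "Fine-KNN", "Cos-KNN")) {
    r <- crossValidate(d$X, d$y, m, runs = 1, folds = 5, seed = 7,
                       positive = "AD")
    expect_gt(r@accuracy, 90)
    expect_gte(r@auc, 0.9)
  }
})

test_that("standardization and fold preprocessing cannot leak test labels", {
  withr::with_seed(21, {
    n <- 100
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rep(c("NC", "AD"), each = n / 2)
  })
  # canary 1: a feature equal to the label (plus hair-thin noise so the
  # discriminant accepts it) leaks 100%
  leak_col <- withr::with_seed(22,
    as.numeric(y == "AD") + rnorm(n, sd = 0.01))
  X_leak <- cbind(X, leak_col)
  r_leak <- crossValidate(X_leak, y, "LD", runs = 1, folds = 5, seed = 1,
                          positive = "AD")
  expect_equal(r_leak@accuracy, 100)
  # canary 2: a preprocessing hook that is only informative if fitted on
  # test data must NOT leak: the transform returns the label column for
  # rows seen during fit and an uninformative constant elsewhere
  rownames(X) <- as.character(seq_len(n))
  label_lookup <- stats::setNames(leak_col, rownames(X))
  preproc <- list(
    fit = function(Xtr, ytr) rownames(Xtr),
    transform = function(state, Xn) {
      seen <- rownames(Xn) %in% state
      out <- ifelse(seen, label_lookup[rownames(Xn)], 0.5)
      matrix(out, ncol = 1)
    })
  r <- crossValidate(X, y, "LD", runs = 2, folds = 5, seed = 2,
                     positive = "AD", preproc = preproc)
  # test rows only ever see the uninformative constant -> chance accuracy
  expect_lt(r@accuracy, 65)
})

test_that("evaluateSuite produces the pairs-by-models grid", {
  withr::with_seed(30, {
    recs <- data.frame(
      label = rep(c("NC", "EMCI", "AD"), each = 20),
      F1 = c(rnorm(20, 0), rnorm(20, 4), rnorm(20, 8)),
      F2 = rnorm(60))
  })
  suite <- evaluateSuite(recs, models = c("LD", "Fine-KNN"),
                         runs = 1, folds = 5, seed = 3)
  expect_length(suite$reports, 6)  # 3 pairs x 2 models
  expect_equal(nrow(suite$metrics), 9)  # 3 pairs x 3 metrics
  expect_equal(nrow(suite$auc), 3)
  # well-separated classes: everything beats chance
  for (r in suite$reports) expect_gt(r@accuracy, 60)
  # disease class is positive: sensitivity refers to EMCI/AD
  expect_error(evaluateSuite(recs[recs$label != "AD", ]), "absent")
})
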