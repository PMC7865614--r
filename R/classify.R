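# Classical binary classifiers and the repeated stratified cross-validation
# harness.
#
# Eight model specifications are supported, with fixed default
# hyperparameters (no tuning): Gaussian naive Bayes; linear discriminant;
# SVMs with linear, quadratic, cubic and medium-Gaussian kernels (box
# constraint 1, standardized inputs, kernel scale "auto" via the median
# heuristic except the Gaussian kernel's manual scale 32); 1-NN with
# Euclidean distance; and 10-NN with cosine distance, both on standardized
# inputs. The positive class is always the disease class of a pair.

MODEL_NAMES <- c("NB", "LD", "L-SVM", "Q-SVM", "C-SVM", "MG-SVM",
                 "Fine-KNN", "Cos-KNN")

#' Construct a model object for one of the supported specifications
#'
#' @param name one of \code{"NB"}, \code{"LD"}, \code{"L-SVM"},
#'   \code{"Q-SVM"}, \code{"C-SVM"}, \code{"MG-SVM"}, \code{"Fine-KNN"},
#'   \code{"Cos-KNN"}.
#' @param ... hyperparameter overrides; only names valid for the chosen
#'   model are accepted (\code{cost}, \code{kernel_scale} for SVMs;
#'   \code{k} for KNNs). Unknown names are an error.
#' @return A list with fields \code{name}, \code{standardize},
#'   \code{fit(X, y)} and \code{score(fit, X)} (higher score = more likely
#'   positive class, the second factor level).
#' @export
makeModel <- function(name, ...) {
  if (!name %in% MODEL_NAMES) {
    stop("unknown model '", name, "'; valid models: ",
         paste(MODEL_NAMES, collapse = ", "))
  }
  over <- list(...)
  valid_hp <- switch(name,
    "NB" = , "LD" = character(0),
    "Fine-KNN" = , "Cos-KNN" = "k",
    c("cost", "kernel_scale"))
  bad <- setdiff(names(over), valid_hp)
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "))
  }
  hp <- switch(name,
    "NB" = list(),
    "LD" = list(),
    "L-SVM" = list(degree = 1, cost = 1, kernel_scale = "auto"),
    "Q-SVM" = list(degree = 2, cost = 1, kernel_scale = "auto"),
    "C-SVM" = list(degree = 3, cost = 1, kernel_scale = "auto"),
    "MG-SVM" = list(cost = 1, kernel_scale = 32),
    "Fine-KNN" = list(k = 1),
    "Cos-KNN" = list(k = 10))
  hp[names(over)] <- over
  standardize <- !(name %in% c("NB", "LD"))

  if (name == "NB") {
    fit <- function(X, y) e1071::naiveBayes(x = as.data.frame(X), y = y)
    score <- function(f, X) {
      # columns of the raw posterior follow the training factor levels;
      # column 2 is the positive class
      stats::predict(f, as.data.frame(X), type = "raw")[, 2]
    }
  } else if (name == "LD") {
    fit <- function(X, y) {
      # lda() rejects predictors whose within-group sd falls below an
      # absolute tolerance; LDA is affine-invariant, so rescale columns to
      # unit overall sd and drop those still (near-)constant within groups
      # (possible for sparse bag-of-features columns)
      osd <- apply(X, 2, stats::sd)
      osd[osd == 0] <- 1
      Xs <- sweep(X, 2, osd, "/")
      wsd <- sqrt(Reduce(`+`, lapply(levels(y), function(cl) {
        Xg <- Xs[y == cl, , drop = FALSE]
        colSums(scale(Xg, scale = FALSE)^2)
      })) / nrow(Xs))
      keep <- wsd > 2e-4
      if (!any(keep)) keep[1] <- TRUE
      # collinear predictors (e.g. histogram columns summing to 1) are
      # handled internally by lda; its warning is uninformative here
      list(lda = suppressWarnings(
             MASS::lda(Xs[, keep, drop = FALSE], grouping = y)),
           keep = keep, osd = osd)
    }
    score <- function(f, X) {
      Xs <- sweep(X, 2, f$osd, "/")
      stats::predict(f$lda, Xs[, f$keep, drop = FALSE])$posterior[, 2]
    }
  } else if (name %in% c("L-SVM", "Q-SVM", "C-SVM", "MG-SVM")) {
    fit <- function(X, y) {
      ks <- hp$kernel_scale
      if (identical(ks, "auto")) ks <- .median_heuristic(X)
      if (name == "MG-SVM") {
        m <- e1071::svm(X, y, kernel = "radial", gamma = 1 / ks^2,
                        cost = hp$cost, scale = FALSE, probability = FALSE)
      } else {
        # Matlab-style polynomial kernel (1 + <x/s, y/s>)^d
        m <- e1071::svm(X / ks, y, kernel = "polynomial",
                        degree = hp$degree, gamma = 1, coef0 = 1,
                        cost = hp$cost, scale = FALSE, probability = FALSE)
      }
      list(svm = m, ks = ks)
    }
    score <- function(f, X) {
      Xs <- if (name == "MG-SVM") X else X / f$ks
      dv <- attr(stats::predict(f$svm, Xs, decision.values = TRUE),
                 "decision.values")
      # e1071 labels the margin "A/B" with positive values favoring A;
      # flip so larger = positive class (second factor level)
      margin_pos <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      sgn <- if (margin_pos == f$svm$levels[2]) 1 else -1
      sgn * dv[, 1]
    }
  } else {  # KNN variants
    fit <- function(X, y) list(X = X, y = y)
    score <- function(f, X) {
      tr <- f$X; te <- X
      if (name == "Cos-KNN") {
        tr <- .l2_rows(tr); te <- .l2_rows(te)
      }
      pred <- class::knn(tr, te, cl = f$y, k = hp$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      pos <- levels(f$y)[2]
      ifelse(pred == pos, pwin, 1 - pwin)
    }
  }
  list(name = name, hyperparameters = hp, standardize = standardize,
       fit = fit, score = score)
}

# median pairwise Euclidean distance (kernel scale "auto"), subsampled for
# large n; guarded against zero
.median_heuristic <- function(X, max_n = 200) {
  n <- nrow(X)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  m <- stats::median(stats::dist(X[idx, , drop = FALSE]))
  if (!is.finite(m) || m <= 0) 1 else m
}

# rows scaled to unit L2 norm (cosine distance ranking == Euclidean on the
# unit sphere); zero rows left as zero
.l2_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  X / ifelse(n > 0, n, 1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique score values (descending), recording
#' (FPR, TPR) at each; AUC is the trapezoid-rule area under the resulting
#' polyline. Grouping tied scores at a single threshold makes the trapezoid
#' area identical to the rank-average Mann-Whitney statistic
#' U/(n1*n2).
#'
#' @param scores numeric vector; larger values indicate the positive class.
#' @param y factor or vector of labels.
#' @param positive label of the positive class (default: second factor
#'   level).
#' @return List with \code{roc_points} (data.frame fpr, tpr) and
#'   \code{auc}.
#' @export
rocAuc <- function(scores, y, positive = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("rocAuc: need both classes")
  if (any(!is.finite(scores))) stop("rocAuc: scores must be finite")
  if (is.null(positive)) positive <- levels(y)[2]
  is_pos <- y == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- is_pos[ord]
  # group ties: cumulative counts at each distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last_of_group]
  fp <- cumsum(!pos)[last_of_group]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Repeated stratified k-fold cross-validation of one model
#'
#' Runs \code{runs} repetitions of stratified \code{folds}-fold
#' cross-validation, reshuffling fold assignments each run from the master
#' seed. All data-dependent preprocessing is fitted on training folds only:
#' per-feature standardization (for models that standardize), and any
#' additional \code{preproc} transform (e.g. a bag-of-features codebook).
#' Confusion counts are recorded per fold; accuracy, sensitivity and
#' specificity are averaged over all folds of all runs, with run-level
#' standard deviations. ROC/AUC is computed from the pooled out-of-fold
#' scores.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels; coerced to a factor with the negative class first.
#' @param model a model from \code{\link{makeModel}} (or a model name).
#' @param runs,folds protocol dimensions (defaults 10 and 10).
#' @param seed integer master seed; identical seeds give identical reports.
#' @param positive label of the positive (disease) class; default: second
#'   factor level of \code{y}.
#' @param preproc optional list with \code{fit(X_train, y_train)} returning
#'   a state and \code{transform(state, X)} returning extra feature columns
#'   appended to X; fitted inside each training fold (no leakage).
#' @return A \linkS4class{CVReport}.
#' @export
crossValidate <- function(X, y, model, runs = 10, folds = 10, seed = 1,
                          positive = NULL, preproc = NULL) {
  if (is.character(model)) model <- makeModel(model)
  X <- as.matrix(X)
  y <- as.factor(as.character(y))
  if (nlevels(y) != 2) stop("crossValidate: need exactly two classes")
  if (!is.null(positive)) {
    y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  }
  pos <- levels(y)[2]
  n_class <- table(y)
  if (any(n_class < folds)) {
    stop("crossValidate: need at least `folds` samples per class ",
         "(have ", paste(n_class, collapse = "/"), ")")
  }
  per_fold <- vector("list", runs * folds)
  pooled_scores <- numeric(0)
  pooled_truth <- character(0)
  withr::with_seed(as.integer(seed), {
    for (run in seq_len(runs)) {
      fold_id <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      for (fold in seq_len(folds)) {
        tr <- fold_id != fold; te <- !tr
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (!is.null(preproc)) {
          st <- preproc$fit(Xtr, y[tr])
          Xtr <- cbind(Xtr, preproc$transform(st, Xtr))
          Xte <- cbind(Xte, preproc$transform(st, Xte))
        }
        if (model$standardize) {
          mu <- colMeans(Xtr)
          sd_ <- apply(Xtr, 2, stats::sd)
          sd_[sd_ == 0] <- 1
          Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
          Xte <- sweep(sweep(Xte, 2, mu), 2, sd_, "/")
        }
        f <- model$fit(Xtr, y[tr])
        sc <- model$score(f, Xte)
        # probability-like scores threshold at 0.5, SVM margins at 0
        thr <- if (model$name %in% c("L-SVM", "Q-SVM", "C-SVM", "MG-SVM"))
          0 else 0.5
        pred <- ifelse(sc > thr, pos, levels(y)[1])
        truth <- y[te]
        tp <- sum(pred == pos & truth == pos)
        fp <- sum(pred == pos & truth != pos)
        tn <- sum(pred != pos & truth != pos)
        fn <- sum(pred != pos & truth == pos)
        per_fold[[(run - 1) * folds + fold]] <-
          data.frame(run = run, fold = fold, TP = tp, FP = fp,
                     TN = tn, FN = fn)
        pooled_scores <- c(pooled_scores, sc)
        pooled_truth <- c(pooled_truth, as.character(truth))
      }
    }
  })
  pf <- do.call(rbind, per_fold)
  acc <- 100 * (pf$TP + pf$TN) / (pf$TP + pf$FP + pf$TN + pf$FN)
  sens <- 100 * pf$TP / (pf$TP + pf$FN)
  spec <- 100 * pf$TN / (pf$TN + pf$FP)
  run_means <- function(v) tapply(v, pf$run, mean, na.rm = TRUE)
  roc <- rocAuc(pooled_scores, factor(pooled_truth, levels = levels(y)),
                positive = pos)
  new("CVReport",
    model = model$name, dataset = paste(rev(levels(y)), collapse = " vs. "),
    runs = as.integer(runs), folds = as.integer(folds), perFold = pf,
    accuracy = mean(acc), sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec, na.rm = TRUE),
    accuracySd = stats::sd(run_means(acc)),
    sensitivitySd = stats::sd(run_means(sens)),
    specificitySd = stats::sd(run_means(spec)),
    rocPoints = roc$roc_points, auc = roc$auc, seed = as.integer(seed))
}

#' Evaluate the full model panel on binary class pairs
#'
#' For each (disease, control) pair and each model specification, runs
#' \code{\link{crossValidate}} on the feature records restricted to the two
#' classes, with the disease class positive.
#'
#' @param records labelled feature data.frame (columns \code{label} plus
#'   numeric features).
#' @param pairs list of character pairs \code{c(positive, negative)},
#'   default the three dementia datasets EMCI vs. NC, AD vs. NC,
#'   AD vs. EMCI.
#' @param models character vector of model names (default: all eight).
#' @param runs,folds,seed protocol parameters.
#' @param feature_cols columns to use as features (default: all numeric).
#' @param preproc optional per-fold preprocessing, see
#'   \code{\link{crossValidate}}.
#' @return List with \code{reports} (list of \linkS4class{CVReport}),
#'   \code{metrics} (long data.frame: dataset, metric, one column per
#'   model) and \code{auc} (data.frame: dataset, one column per model).
#' @export
evaluateSuite <- function(records,
                          pairs = list(c("EMCI", "NC"), c("AD", "NC"),
                                       c("AD", "EMCI")),
                          models = MODEL_NAMES,
                          runs = 10, folds = 10, seed = 1,
                          feature_cols = NULL, preproc = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  reports <- list()
  for (pair in pairs) {
    miss <- setdiff(pair, unique(records$label))
    if (length(miss)) stop("evaluateSuite: class absent from records: ",
                           paste(miss, collapse = ", "))
    sub <- records[records$label %in% pair, , drop = FALSE]
    X <- as.matrix(sub[, feature_cols, drop = FALSE])
    for (m in models) {
      rep_ <- crossValidate(X, sub$label, m, runs = runs, folds = folds,
                            seed = seed, positive = pair[1],
                            preproc = preproc)
      rep_@dataset <- paste(pair[1], "vs.", pair[2])
      reports[[paste(rep_@dataset, m, sep = " | ")]] <- rep_
    }
  }
  ds_names <- vapply(pairs, function(p) paste(p[1], "vs.", p[2]),
                     character(1))
  metric_rows <- list()
  for (ds in ds_names) {
    for (met in c("Accuracy", "Sensitivity", "Specificity")) {
      vals <- vapply(models, function(m) {
        r <- reports[[paste(ds, m, sep = " | ")]]
        switch(met, Accuracy = r@accuracy, Sensitivity = r@sensitivity,
               Specificity = r@specificity)
      }, numeric(1))
      metric_rows[[paste(ds, met)]] <-
        data.frame(dataset = ds, metric = met, t(vals),
                   check.names = FALSE)
    }
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  auc <- do.call(rbind, lapply(ds_names, function(ds) {
    vals <- vapply(models, function(m)
      reports[[paste(ds, m, sep = " | ")]]@auc, numeric(1))
    data.frame(dataset = ds, t(vals), check.names = FALSE)
  }))
  list(reports = reports, metrics = metrics, auc = auc)
}
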