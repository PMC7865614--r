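# End-to-end pipeline: preprocess -> align -> asymmetry -> features ->
# evaluate, with a single validated configuration object and deterministic
# outputs under a fixed seed.

.CONFIG_DEFAULTS <- list(
  resize_size = 256,
  threshold_band = c(30, 200),
  binarize_threshold = 0,
  angle_range = 15,
  angle_step = 0.5,
  weighted_centroid = FALSE,
  wavelet = "haar",
  dwt_level = 1,
  idm_normalized = TRUE,
  bof_k = 0,            # 0 disables bag-of-features columns
  models = MODEL_NAMES,
  pairs = list(c("EMCI", "NC"), c("AD", "NC"), c("AD", "EMCI")),
  runs = 10,
  folds = 10,
  seed = 1
)

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults and applies overrides; unknown keys are
#' rejected before any computation. The configuration round-trips through
#' JSON (\code{\link{writeConfig}} / \code{\link{readConfig}}).
#'
#' @param ... named overrides of the defaults: \code{resize_size},
#'   \code{threshold_band} (length-2 lower/upper), \code{binarize_threshold}
#'   ("auto" or intensity), \code{angle_range}, \code{angle_step},
#'   \code{weighted_centroid}, \code{wavelet}, \code{dwt_level},
#'   \code{idm_normalized}, \code{bof_k} (0 = stats features only),
#'   \code{models}, \code{pairs}, \code{runs}, \code{folds}, \code{seed}.
#' @return Named list of validated configuration values.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- .CONFIG_DEFAULTS
  cfg[names(over)] <- over
  stopifnot(length(cfg$threshold_band) == 2,
            cfg$threshold_band[1] < cfg$threshold_band[2],
            cfg$angle_step > 0, cfg$runs >= 1, cfg$folds >= 2,
            cfg$bof_k >= 0)
  bad_models <- setdiff(cfg$models, MODEL_NAMES)
  if (length(bad_models)) {
    stop("unknown model(s) in config: ", paste(bad_models, collapse = ", "))
  }
  cfg
}

#' Write a pipeline configuration to JSON
#' @param cfg configuration from \code{\link{pipelineConfig}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a pipeline configuration from JSON
#' @param path JSON file written by \code{\link{writeConfig}} (or by hand).
#' @return Validated configuration list.
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$pairs) && is.matrix(raw$pairs)) {
    raw$pairs <- lapply(seq_len(nrow(raw$pairs)), function(i) raw$pairs[i, ])
  }
  if (!is.null(raw$pairs) && is.list(raw$pairs)) {
    raw$pairs <- lapply(raw$pairs, unlist)
  }
  do.call(pipelineConfig, raw)
}

#' Run the full asymmetry pipeline on a labelled image set
#'
#' Executes preprocess (normalize/resize + skull strip), symmetry alignment,
#' asymmetry-map extraction, feature generation and the cross-validated
#' model panel, writing all artifacts under \code{out_dir}:
#' \code{features.csv}, \code{feature_means.csv} (per-class means of the
#' min-max normalized features), \code{metrics.csv} (datasets x models grid
#' of accuracy/sensitivity/specificity), \code{auc.csv},
#' \code{alignment.csv} (per-image pose and symmetry score),
#' \code{pareto.csv} and \code{config.json} (provenance: full config +
#' seed). Reruns with the same inputs and config produce byte-identical
#' CSVs.
#'
#' With \code{cfg$bof_k > 0}, bag-of-features histograms are appended to
#' the statistical features inside each cross-validation fold, with the
#' codebook fitted on training-fold maps only (no leakage).
#'
#' @param input either a list of \linkS4class{PhantomBundle}s /
#'   \linkS4class{GrayImage}s with \code{labels}, or a directory containing
#'   images and a \code{manifest.csv} with columns filename,label.
#' @param cfg configuration from \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if needed).
#' @param labels class labels, required when \code{input} is a list of
#'   GrayImages; ignored for PhantomBundles (their spec labels are used).
#' @param evaluate run the classification stage (default TRUE).
#' @return Invisibly, a list with \code{features}, \code{alignments},
#'   \code{pareto}, and (if evaluated) \code{metrics}, \code{auc},
#'   \code{reports}.
#' @export
runPipeline <- function(input, cfg = pipelineConfig(), out_dir,
                        labels = NULL, evaluate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ## ---- ingest ----
  if (is.character(input)) {
    manifest <- file.path(input, "manifest.csv")
    if (!file.exists(manifest)) {
      stop("runPipeline [ingest]: no manifest.csv in ", input)
    }
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    images <- lapply(file.path(input, man$filename), loadImage)
    labels <- man$label
  } else if (all(vapply(input, is, logical(1), "PhantomBundle"))) {
    images <- lapply(input, function(b) b@image)
    labels <- vapply(input, function(b) b@spec$label, character(1))
  } else {
    images <- input
    if (is.null(labels)) stop("runPipeline [ingest]: labels required")
  }
  ## ---- preprocess ----
  pre <- lapply(images, function(im) {
    skullStrip(normalizeResize(im, size = cfg$resize_size),
               band = cfg$threshold_band)
  })
  ## ---- align + asymmetry ----
  aligned <- lapply(pre, function(im) {
    alignAndExtract(im, threshold = cfg$binarize_threshold,
                    angle_range = cfg$angle_range,
                    angle_step = cfg$angle_step,
                    weighted_centroid = cfg$weighted_centroid)
  })
  alignments <- do.call(rbind, lapply(seq_along(aligned), function(i) {
    a <- aligned[[i]]$alignment
    data.frame(source_id = aligned[[i]]$aligned@sourceId,
               label = labels[i],
               centroid_row = a@centroidRow, centroid_col = a@centroidCol,
               shift_row = a@shiftRow, shift_col = a@shiftCol,
               angle_deg = a@angleDeg, symmetry_score = a@symmetryScore)
  }))
  maps <- lapply(aligned, `[[`, "map")
  origs <- lapply(aligned, `[[`, "aligned")
  ## ---- features ----
  feats <- featureTable(maps, origs, labels, wavelet = cfg$wavelet,
                        level = cfg$dwt_level,
                        idm_normalized = cfg$idm_normalized)
  pareto <- msePareto(feats)
  feats_out <- feats
  if (cfg$bof_k > 0 && !evaluate) {
    # standalone feature export: corpus-level codebook, one histogram
    # column per visual word (the evaluated path instead refits the
    # codebook inside each training fold)
    cb <- bofFit(maps, k = cfg$bof_k, seed = cfg$seed)
    H <- t(vapply(maps, bofEncode, numeric(cfg$bof_k), codebook = cb))
    colnames(H) <- sprintf("bof_%03d", seq_len(cfg$bof_k) - 1)
    feats_out <- cbind(feats, as.data.frame(H))
  }
  utils::write.csv(feats_out, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(classFeatureMeans(normalizeFeatures(feats)),
                   file.path(out_dir, "feature_means.csv"),
                   row.names = FALSE)
  utils::write.csv(alignments, file.path(out_dir, "alignment.csv"),
                   row.names = FALSE)
  utils::write.csv(pareto, file.path(out_dir, "pareto.csv"),
                   row.names = FALSE)
  writeConfig(cfg, file.path(out_dir, "config.json"))
  result <- list(features = feats, alignments = alignments, pareto = pareto)
  ## ---- evaluate ----
  if (evaluate) {
    preproc <- NULL
    if (cfg$bof_k > 0) {
      # per-fold bag-of-features: descriptors are computed once per map;
      # codebook fitting and encoding run inside each training fold
      desc <- lapply(maps, surfDescriptors)
      row_of <- seq_len(nrow(feats))
      preproc <- local({
        desc <- desc
        list(
          fit = function(Xtr, ytr) {
            idx <- match(rownames(Xtr), as.character(row_of))
            bofFit(NULL, k = cfg$bof_k, seed = cfg$seed,
                   descriptors = do.call(rbind, desc[idx]))
          },
          transform = function(cb, X) {
            idx <- match(rownames(X), as.character(row_of))
            t(vapply(idx, function(i) {
              bofEncode(NULL, cb, descriptors = desc[[i]])
            }, numeric(cb@k)))
          })
      })
    }
    Xall <- as.matrix(feats[, STAT_FEATURE_NAMES])
    rownames(Xall) <- as.character(seq_len(nrow(Xall)))
    records <- data.frame(label = feats$label, Xall, check.names = FALSE)
    suite <- evaluateSuite(records, pairs = cfg$pairs, models = cfg$models,
                           runs = cfg$runs, folds = cfg$folds,
                           seed = cfg$seed,
                           feature_cols = STAT_FEATURE_NAMES,
                           preproc = preproc)
    .write_metrics_csv(suite$metrics, file.path(out_dir, "metrics.csv"))
    .write_metrics_csv(suite$auc, file.path(out_dir, "auc.csv"))
    result <- c(result, suite)
  }
  invisible(result)
}

# fixed-format CSV writer so reruns are byte-identical
.write_metrics_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Write a phantom cohort to disk as PNGs plus a manifest
#'
#' @param bundles list of \linkS4class{PhantomBundle}s.
#' @param out_dir output directory.
#' @return Path of the written manifest.csv, invisibly.
#' @export
writeCohort <- function(bundles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    fn <- sprintf("phantom_%04d_%s.png", i, b@spec$label)
    writeImagePNG(b@image, file.path(out_dir, fn))
    data.frame(filename = fn, label = b@spec$label,
               amplitude = b@spec$asymmetry_amplitude,
               n_lesions = b@spec$n_lesions,
               rotation_deg = b@truthPose$rotation_deg,
               shift_row = b@truthPose$shift[1],
               shift_col = b@truthPose$shift[2],
               noise_sigma = b@spec$noise_sigma,
               seed = b@spec$seed)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(file.path(out_dir, "manifest.csv"))
}
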