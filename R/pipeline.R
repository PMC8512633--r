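# Pipeline configuration, ROI dataset construction, the model fitting
# front-end, and batch / sliding-window detection.

#' Pipeline configuration
#'
#' Bundles the per-stage settings. `window_s`/`hop_s` control the
#' sliding-window inference mode: 1.5 s windows advancing by 1.0 s, i.e.
#' 0.5 s overlap between consecutive windows.
#'
#' @param vmd A [vmd_config()].
#' @param band A [band_config()].
#' @param roi List: `min_prominence_frac`, `label_tolerance_s`.
#' @param features List: `max_features`, `sfs_tol`, `sfs_folds`, `sfs_maxdepth`.
#' @param detector List: `train_frac`, `cv_folds`, `per_tree_sample_frac`,
#'   `ensemble_size`, `rlc_absolute`, `rlc_half_window` (`NULL`: scale 4
#'   samples at 360 Hz with fs).
#' @param evaluation List: `tolerance_s` matching tolerance.
#' @param window_s Sliding window length, seconds.
#' @param hop_s Sliding window hop, seconds (`window_s > hop_s > 0`).
#' @param dedup_s Refractory merge distance for duplicate detections, seconds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vmd = vmd_config(),
                            band = band_config(),
                            roi = list(min_prominence_frac = 1e-4,
                                       label_tolerance_s = 0.05),
                            features = list(max_features = 8, sfs_tol = 1e-4,
                                            sfs_folds = 5, sfs_maxdepth = 5),
                            detector = list(train_frac = 0.8, cv_folds = 10,
                                            per_tree_sample_frac = 0.75,
                                            ensemble_size = 16,
                                            rlc_absolute = FALSE,
                                            rlc_half_window = NULL),
                            evaluation = list(tolerance_s = 0.15),
                            window_s = 1.5, hop_s = 1.0, dedup_s = 0.2) {
  stopifnot(inherits(vmd, "vmd_config"), inherits(band, "band_config"),
            window_s > hop_s, hop_s > 0, dedup_s > 0)
  structure(list(vmd = vmd, band = band, roi = roi, features = features,
                 detector = detector, evaluation = evaluation,
                 window_s = window_s, hop_s = hop_s, dedup_s = dedup_s),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised sections mirror [pipeline_config()]: `vmd`, `dmse`
#' (`fl`/`fh`), `roi`, `features`, `detector`, `evaluation`, and top-level
#' `window_s`/`hop_s`/`dedup_s`. Missing entries keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  vmd <- do.call(vmd_config, utils::modifyList(
    unclass(defaults$vmd), y$vmd %||% list()))
  band <- do.call(band_config, utils::modifyList(
    unclass(defaults$band), y$dmse %||% list()))
  pipeline_config(
    vmd = vmd, band = band,
    roi = utils::modifyList(defaults$roi, y$roi %||% list()),
    features = utils::modifyList(defaults$features, y$features %||% list()),
    detector = utils::modifyList(defaults$detector, y$detector %||% list()),
    evaluation = utils::modifyList(defaults$evaluation, y$evaluation %||% list()),
    window_s = y$window_s %||% defaults$window_s,
    hop_s = y$hop_s %||% defaults$hop_s,
    dedup_s = y$dedup_s %||% defaults$dedup_s)
}

# Stages 2-4 on one signal: QRS component -> peaks -> windows -> features.
# Returns list(component, windows-with-features); windows may have 0 rows,
# and an empty mode selection yields 0 rows (the "no QRS component" case).
roi_features <- function(record, config) {
  comp <- qrs_component(record, vmd = config$vmd, band = config$band)
  peaks <- find_energy_peaks(comp, config$roi$min_prominence_frac)
  win <- aws_windows(peaks, length(comp$Re))
  list(component = comp, windows = extract_features(win, comp))
}

#' Build a labelled ROI feature dataset from annotated records
#'
#' Runs decomposition, dynamic mode selection, peak finding, adaptive
#' windowing, labelling and feature extraction on each record (whole-record
#' batch mode) and stacks the results.
#'
#' @param records List of annotated [ecg_record]s.
#' @param config A [pipeline_config()].
#' @return Data frame: one row per ROI window with feature columns, `label`,
#'   `beat_type`, and `record` (record name).
#' @export
build_roi_dataset <- function(records, config = pipeline_config()) {
  if (inherits(records, "ecg_record")) records <- list(records)
  parts <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "ecg_record"))
    if (is.null(rec$annotations) || nrow(rec$annotations) == 0)
      stop("record '", rec$name, "' has no beat annotations", call. = FALSE)
    rf <- roi_features(rec, config)
    win <- label_windows(rf$windows, rec$annotations, rec$fs,
                         config$roi$label_tolerance_s)
    win$record <- if (nrow(win) > 0) rec$name else character(0)
    win
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Fit the R-peak detection model
#'
#' End-to-end training: builds the labelled ROI dataset from annotated
#' records, makes a stratified train/test split with cross-validation folds,
#' runs sequential forward selection on the training rows, trains the
#' feature-subset tree ensemble, and evaluates window classification on the
#' held-out rows.
#'
#' @param records List of annotated [ecg_record]s (or one record).
#' @param config A [pipeline_config()].
#' @param seed Integer seed controlling the split, SFS folds and per-tree
#'   sampling.
#' @return An object of class `rpeak_model`: `ensemble`, `sfs`, `config`,
#'   `fs`, `split` (row indices), `test_metrics`, `test_auc`, `n_windows`.
#' @export
fit_rpeak_model <- function(records, config = pipeline_config(), seed = 1L) {
  if (inherits(records, "ecg_record")) records <- list(records)
  fs <- records[[1]]$fs
  stopifnot(all(vapply(records, function(r) r$fs == fs, logical(1))))

  dataset <- build_roi_dataset(records, config)
  if (length(unique(dataset$label)) < 2)
    stop("ROI dataset is single-class; cannot train a classifier", call. = FALSE)

  strata <- ifelse(dataset$label == "R", dataset$beat_type, "False-R")
  split <- split_dataset(strata, train_frac = config$detector$train_frac,
                         cv_folds = config$detector$cv_folds, seed = seed)
  train <- dataset[split$train, , drop = FALSE]
  test <- dataset[split$test, , drop = FALSE]

  sfs <- sfs_select(train, max_features = config$features$max_features,
                    tol = config$features$sfs_tol,
                    folds = config$features$sfs_folds,
                    maxdepth = config$features$sfs_maxdepth, seed = seed)
  ensemble <- train_ensemble(train, sfs$selected, split$fold_id,
                             ensemble_size = config$detector$ensemble_size,
                             sample_frac = config$detector$per_tree_sample_frac,
                             seed = seed)

  test_metrics <- NULL
  test_auc <- NA_real_
  if (nrow(test) > 0 && length(unique(test$label)) == 2) {
    pred <- predict(ensemble, test)
    counts <- confusion_counts(
      TP = sum(pred == "R" & test$label == "R"),
      FP = sum(pred == "R" & test$label == "False-R"),
      TN = sum(pred == "False-R" & test$label == "False-R"),
      FN = sum(pred == "False-R" & test$label == "R"))
    test_metrics <- suppressWarnings(classification_metrics(counts))
    test_auc <- auc_score(predict(ensemble, test, type = "votes"), test$label)
  }

  structure(list(ensemble = ensemble, sfs = sfs, config = config, fs = fs,
                 split = split, test_metrics = test_metrics,
                 test_auc = test_auc, n_windows = nrow(dataset), seed = seed),
            class = "rpeak_model")
}

#' @export
print.rpeak_model <- function(x, ...) {
  cat(sprintf("<rpeak_model>  fs %g Hz, %d ROI windows (%d train / %d test)\n",
              x$fs, x$n_windows, length(x$split$train), length(x$split$test)))
  cat("  features:", paste(x$sfs$selected, collapse = ", "), "\n")
  cat(sprintf("  ensemble: %d trees (CV accuracy %.4f - %.4f)\n",
              length(x$ensemble$trees), min(x$ensemble$cv_accuracy),
              max(x$ensemble$cv_accuracy)))
  if (!is.null(x$test_metrics))
    cat(sprintf("  held-out windows: Se %.2f%%  P %.2f%%  Acc %.2f%%  AUC %.4f\n",
                round2(x$test_metrics$sensitivity), round2(x$test_metrics$precision),
                round2(x$test_metrics$accuracy), x$test_auc))
  invisible(x)
}

#' @export
summary.rpeak_model <- function(object, ...) {
  print(object)
  cat("\nSFS criterion trajectory:\n")
  print(object$sfs)
  cat("\nEnsemble subsets (by CV accuracy):\n")
  for (i in seq_along(object$ensemble$trees))
    cat(sprintf("  %2d. acc %.4f  {%s}\n", i, object$ensemble$cv_accuracy[i],
                paste(object$ensemble$subsets[[i]], collapse = ", ")))
  invisible(object)
}

# merge detections closer than `refractory` samples, keeping the one with
# the larger (corrected) raw amplitude
dedup_detections <- function(locations, amplitude, refractory) {
  if (length(locations) == 0) return(integer())
  ord <- order(locations)
  locations <- locations[ord]; amplitude <- amplitude[ord]
  keep_loc <- locations[1]; keep_amp <- amplitude[1]
  out <- integer()
  for (i in seq_along(locations)[-1]) {
    if (locations[i] - keep_loc < refractory) {
      if (amplitude[i] > keep_amp) { keep_loc <- locations[i]; keep_amp <- amplitude[i] }
    } else {
      out <- c(out, keep_loc)
      keep_loc <- locations[i]; keep_amp <- amplitude[i]
    }
  }
  c(out, keep_loc)
}

#' Detect R peaks in a record with a trained model
#'
#' `"batch"` mode (the default) runs the stages once over the whole record.
#' `"sliding"` mode emulates real-time operation: the record is cut into
#' overlapping windows (`window_s` long, advancing by `hop_s`); stages 2-5
#' run per window and duplicate detections from the overlaps are merged
#' (detections closer than `dedup_s` keep the higher corrected amplitude).
#' The band test is noticeably more fragile on 1.5 s segments (the
#' instantaneous-frequency spread grows on short windows), so sliding mode
#' trades sensitivity for latency; see the methods vignette. Either way,
#' classified R windows yield their energy-peak locations, which are snapped
#' to the raw-signal maximum by [rlc_correct()]. Segments in which no mode
#' passes the band test contribute zero detections.
#'
#' @param record An [ecg_record] at the model's sampling rate.
#' @param model A fitted [fit_rpeak_model()].
#' @param mode `"batch"` or `"sliding"`.
#' @return Sorted, strictly increasing integer vector of corrected R sample
#'   indices.
#' @export
detect_rpeaks <- function(record, model, mode = c("batch", "sliding")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "ecg_record"), inherits(model, "rpeak_model"))
  if (record$fs != model$fs)
    stop("record fs (", record$fs, " Hz) differs from model fs (",
         model$fs, " Hz)", call. = FALSE)
  config <- model$config
  n <- length(record$samples)
  raw_locs <- integer()
  n_empty <- 0L

  segment_detect <- function(x, offset) {
    rec <- ecg_record(x, fs = record$fs, name = record$name)
    rf <- roi_features(rec, config)
    if (length(rf$component$selected) == 0) {
      n_empty <<- n_empty + 1L
      return(integer())
    }
    win <- rf$windows
    if (nrow(win) == 0) return(integer())
    pred <- predict(model$ensemble, win)
    win$location[pred == "R"] + offset
  }

  if (mode == "batch") {
    raw_locs <- segment_detect(record$samples, 0L)
  } else {
    win_n <- round(config$window_s * record$fs)
    hop_n <- round(config$hop_s * record$fs)
    if (n <= win_n) {
      raw_locs <- segment_detect(record$samples, 0L)
    } else {
      starts <- seq(1L, n - win_n + 1L, by = hop_n)
      if (tail(starts, 1) < n - win_n + 1L) starts <- c(starts, n - win_n + 1L)
      raw_locs <- unlist(lapply(starts, function(s)
        segment_detect(record$samples[s:(s + win_n - 1L)], s - 1L)))
    }
  }
  if (n_empty > 0)
    warning(n_empty, " segment(s) had no mode in the QRS band; ",
            "zero detections emitted there", call. = FALSE)
  if (length(raw_locs) == 0) return(integer())

  corrected <- rlc_correct(record, sort(unique(raw_locs)),
                           half_window = config$detector$rlc_half_window,
                           absolute = isTRUE(config$detector$rlc_absolute))
  amp <- if (isTRUE(config$detector$rlc_absolute))
    abs(record$samples - stats::median(record$samples))[corrected]
  else record$samples[corrected]
  sort(unique(dedup_detections(corrected, amp, round(config$dedup_s * record$fs))))
}

#' @rdname detect_rpeaks
#' @param object A fitted `rpeak_model`.
#' @param ... Passed on (e.g. `mode`).
#' @export
predict.rpeak_model <- function(object, record, ...) {
  detect_rpeaks(record, object, ...)
}
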