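# Per-ROI feature extraction (25 features) and sequential forward selection.
#
# Statistics use the population forms as defined for the feature table:
# sigma with divisor N; kurtosis and skewness with divisor (N-1)*sigma^4 and
# (N-1)*sigma^3. Degenerate cases: sigma = 0 caps the SNR at 1e6 and zeroes
# kurtosis/skewness; a constant window has entropy 0.

FEATURE_NAMES <- c(
  "FhP", "FfP", "FpP", "FwP",            # peak: height, freq, prominence, width
  "FpD", "FfD",                          # distances to previous/next peak
  "FmuE", "FsdE", "FsnrE", "FrmsE", "FpowE", "FareaE", "FentE", "FkurtE", "FskewE",
  "FmuF", "FsdF", "FsnrF", "FrmsF", "FpowF", "FareaF", "FentF", "FkurtF", "FskewF",
  "FsnrS"                                # window-level signal SNR: sum(Re)/sum(Rn)
)

SNR_CAP <- 1e6

window_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  snr <- if (sigma == 0) SNR_CAP else mu / sigma
  rms <- sqrt(sum(x^2) / n)
  pow <- sum(x^2) / n
  area <- sum(x)
  # entropy: shift to non-negative, normalise to a probability vector
  shifted <- x - min(x)
  s <- sum(shifted)
  ent <- if (s == 0) 0 else {
    p <- shifted / s
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (sigma == 0) {
    kur <- 0; ske <- 0
  } else {
    kur <- sum((x - mu)^4) / ((n - 1) * sigma^4)
    ske <- sum((x - mu)^3) / ((n - 1) * sigma^3)
  }
  c(mu = mu, sd = sigma, snr = snr, rms = rms, pow = pow, area = area,
    ent = ent, kurt = kur, skew = ske)
}

#' Extract the 25-feature vector for each ROI window
#'
#' Four peak features (in-band energy and frequency at the peak, prominence,
#' width), two inter-peak distances (samples to the previous and next peak;
#' at record edges the record-median peak distance is substituted), nine
#' window statistics over the energy slice `Re[start:end]` and nine over the
#' frequency slice `Rw[start:end]` (mean, sd, SNR, RMS, power, area, Shannon
#' entropy, kurtosis, skewness), and the window signal-to-noise ratio
#' `sum(Re)/sum(Rn)` over the slice.
#'
#' @param windows Data frame from [aws_windows()] (optionally labelled).
#' @param component The `qrs_component` the windows were found in.
#' @return `windows` with 25 feature columns appended (see `FEATURE_NAMES`).
#' @export
extract_features <- function(windows, component) {
  stopifnot(inherits(component, "qrs_component"))
  n <- nrow(windows)
  feat <- matrix(NA_real_, n, length(FEATURE_NAMES),
                 dimnames = list(NULL, FEATURE_NAMES))
  if (n == 0) return(cbind(windows, as.data.frame(feat)))

  locs <- windows$location
  gaps <- diff(locs)
  med_gap <- if (length(gaps) > 0) stats::median(gaps) else length(component$Re)
  prev_d <- c(med_gap, gaps)
  next_d <- c(gaps, med_gap)

  for (i in seq_len(n)) {
    idx <- windows$start[i]:windows$end[i]
    es <- window_stats(component$Re[idx])
    fsb <- window_stats(component$Rw[idx])
    rn_sum <- sum(component$Rn[idx])
    re_sum <- sum(component$Re[idx])
    snr_s <- if (rn_sum == 0) SNR_CAP else re_sum / rn_sum
    feat[i, ] <- c(component$Re[locs[i]], component$Rw[locs[i]],
                   windows$prominence[i], windows$width[i],
                   prev_d[i], next_d[i], es, fsb, snr_s)
  }
  cbind(windows, as.data.frame(feat))
}

# 0/1-loss cross-validated MSE of a depth-limited tree wrapper on the given
# feature columns. Folds are fixed by the caller for determinism.
wrapper_cv_mse <- function(data, cols, fold_id, maxdepth = 5) {
  err <- 0L
  total <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- data[fold_id != f, c(cols, "label"), drop = FALSE]
    tr$label <- factor(tr$label, levels = c("False-R", "R"))
    va <- data[fold_id == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2) {
      pred <- rep(as.character(tr$label[1]), nrow(va))
    } else {
      fit <- rpart::rpart(label ~ ., data = tr, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = 0, xval = 0,
                            minsplit = 4, minbucket = 2))
      pred <- as.character(predict(fit, va, type = "class"))
    }
    err <- err + sum(pred != va$label)
    total <- total + nrow(va)
  }
  err / total
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step the feature whose addition
#' minimises the cross-validated misclassification MSE of a depth-limited
#' decision tree is added, until `max_features` are selected or the MSE
#' improvement falls below `tol`.
#'
#' @param features Data frame containing the feature columns and a `label`
#'   column with both classes (`"R"`, `"False-R"`).
#' @param max_features Upper bound on selected features (default 8).
#' @param tol Minimum MSE improvement to keep adding (default 1e-4).
#' @param folds Cross-validation folds for the wrapper (default 5).
#' @param maxdepth Depth limit of the wrapper tree (default 5).
#' @param candidates Feature columns to search (default the 25 standard ones).
#' @param seed Seed fixing the CV fold assignment.
#' @return An object of class `sfs_result`: `selected` (ordered names),
#'   `mse` (criterion trajectory, one value per step).
#' @export
sfs_select <- function(features, max_features = 8, tol = 1e-4, folds = 5,
                       maxdepth = 5, candidates = FEATURE_NAMES, seed = 1L) {
  stopifnot(all(candidates %in% names(features)), "label" %in% names(features))
  if (length(unique(features$label)) < 2)
    stop("SFS needs both classes in `features$label`", call. = FALSE)
  if (max_features > length(candidates)) max_features <- length(candidates)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(features)))

  selected <- character()
  trajectory <- numeric()
  best_prev <- Inf
  while (length(selected) < max_features) {
    remaining <- setdiff(candidates, selected)
    mses <- vapply(remaining, function(f)
      wrapper_cv_mse(features, c(selected, f), fold_id, maxdepth), numeric(1))
    best <- which.min(mses)
    if (length(selected) > 0 && best_prev - mses[best] < tol) break
    selected <- c(selected, remaining[best])
    trajectory <- c(trajectory, unname(mses[best]))
    best_prev <- unname(mses[best])
    if (best_prev == 0) break
  }
  structure(list(selected = selected, mse = trajectory), class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat("<sfs_result>  selected features (in order):\n")
  for (i in seq_along(x$selected))
    cat(sprintf("  %d. %-8s MSE %.5f\n", i, x$selected[i], x$mse[i]))
  invisible(x)
}
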