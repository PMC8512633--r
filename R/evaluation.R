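# Detection/annotation matching, confusion-matrix metrics, HRV statistics,
# and rank-based AUC.

#' Match detected R peaks to annotated beats
#'
#' Greedy one-to-one nearest matching: candidate pairs within
#' `round(tolerance_s * fs)` samples are taken in order of increasing
#' distance, each detection and annotation used at most once. Matched pairs
#' are TP, unmatched detections FP, unmatched annotations FN.
#'
#' @param detected Sorted integer vector of detected R sample indices.
#' @param annotated Sorted integer vector of annotated R sample indices.
#' @param fs Sampling rate, Hz.
#' @param tolerance_s Matching tolerance in seconds (default 0.15, the
#'   conventional QRS-evaluation window).
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN` (0 here), `FN`, plus `pairs` (matched index pairs) and
#'   `tolerance_samples`.
#' @export
match_detections <- function(detected, annotated, fs, tolerance_s = 0.15) {
  tol <- round(tolerance_s * fs)
  nd <- length(detected)
  na <- length(annotated)
  pairs <- NULL
  if (nd > 0 && na > 0) {
    cand <- do.call(rbind, lapply(seq_len(nd), function(i) {
      j <- which(abs(annotated - detected[i]) <= tol)
      if (length(j) == 0) return(NULL)
      cbind(i = i, j = j, d = abs(annotated[j] - detected[i]))
    }))
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand[, "d"], cand[, "i"], cand[, "j"]), , drop = FALSE]
      used_i <- logical(nd); used_j <- logical(na)
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (!used_i[i] && !used_j[j]) {
          used_i[i] <- TRUE; used_j[j] <- TRUE; keep[r] <- TRUE
        }
      }
      pairs <- cand[keep, c("i", "j"), drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  confusion_counts(TP = tp, FP = nd - tp, TN = 0L, FN = na - tp,
                   pairs = pairs, tolerance_samples = tol)
}

#' Confusion counts container
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @param ... Extra fields (e.g. matched pairs) stored alongside.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN, ...) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 TN = as.numeric(TN), FN = as.numeric(FN), ...),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts>  TP %g  FP %g  TN %g  FN %g\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes, as percentages: sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, detection error rate `(FP+FN)/TP`, accuracy
#' `TP/(TP+FP+FN)`, specificity `TN/(TN+FP)`, and recall `TP/(TP+TN)`.
#' Note the accuracy, DER and recall forms are those used in this method's
#' evaluation protocol (accuracy ignores TN; recall relates correctly
#' detected R to all correctly classified windows), not the textbook ones.
#' A metric whose denominator is zero is returned as `NaN` with a warning.
#' Values are kept at full precision; the print method rounds to 2 decimals.
#'
#' @param counts A [confusion_counts()] (TN optional, default 0).
#' @return An object of class `metrics_report` with fields `sensitivity`,
#'   `specificity`, `precision`, `recall`, `der`, `accuracy` (percent).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  structure(list(
    sensitivity = 100 * ratio(tp, tp + fn, "sensitivity"),
    specificity = 100 * ratio(tn, tn + fp, "specificity"),
    precision   = 100 * ratio(tp, tp + fp, "precision"),
    recall      = 100 * ratio(tp, tp + tn, "recall"),
    der         = 100 * ratio(fp + fn, tp, "DER"),
    accuracy    = 100 * ratio(tp, tp + fp + fn, "accuracy"),
    counts      = counts
  ), class = "metrics_report")
}

# round half-up at 2 decimals (reporting layer only)
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> (%)\n")
  for (m in c("sensitivity", "specificity", "precision", "recall", "der", "accuracy"))
    cat(sprintf("  %-12s %6.2f\n", m, round2(x[[m]])))
  invisible(x)
}

#' Heart-rate-variability statistics from R-peak locations
#'
#' R-R intervals are `diff(locations) / fs` seconds. With `N` peaks (hence
#' `N-1` intervals): MRR is the mean interval, SDNN the standard deviation
#' about MRR with divisor `N-1`, RMSSD the root mean square of the `N-2`
#' successive interval differences with divisor `N-2`.
#'
#' @param r_locations Sorted integer sample indices of R peaks.
#' @param fs Sampling rate, Hz.
#' @return An object of class `hrv_report` with `mrr`, `sdnn`, `rmssd`
#'   (seconds) and `n_intervals`. `rmssd` is `NaN` with fewer than 3 peaks.
#' @export
hrv_metrics <- function(r_locations, fs) {
  if (length(r_locations) < 2)
    stop("need at least 2 R locations for R-R intervals", call. = FALSE)
  rr <- diff(as.numeric(r_locations)) / fs
  mrr <- mean(rr)
  sdnn <- sqrt(sum((rr - mrr)^2) / length(rr))
  rmssd <- if (length(rr) >= 2) sqrt(mean(diff(rr)^2)) else NaN
  structure(list(mrr = mrr, sdnn = sdnn, rmssd = rmssd,
                 n_intervals = length(rr)),
            class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("<hrv_report>  MRR %.4f s  SDNN %.4f s  RMSSD %.4f s  (%d intervals)\n",
              x$mrr, x$sdnn, x$rmssd, x$n_intervals))
  invisible(x)
}

#' Pool or average HRV over several records
#'
#' `"pooled"` concatenates all R-R intervals before computing the three
#' statistics; `"mean"` computes them per record and averages.
#'
#' @param locations_list List of R-location vectors, one per record.
#' @param fs Sampling rate, Hz (scalar or one per record).
#' @param mode `"pooled"` or `"mean"`.
#' @return An `hrv_report`-like list.
#' @export
aggregate_hrv <- function(locations_list, fs, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  fs <- rep_len(fs, length(locations_list))
  if (mode == "pooled") {
    rr <- unlist(lapply(seq_along(locations_list), function(i)
      diff(as.numeric(locations_list[[i]])) / fs[i]))
    mrr <- mean(rr)
    return(structure(list(mrr = mrr,
                          sdnn = sqrt(sum((rr - mrr)^2) / length(rr)),
                          rmssd = sqrt(mean(diff(rr)^2)),
                          n_intervals = length(rr)),
                     class = "hrv_report"))
  }
  reps <- lapply(seq_along(locations_list), function(i)
    hrv_metrics(locations_list[[i]], fs[i]))
  structure(list(mrr = mean(vapply(reps, `[[`, numeric(1), "mrr")),
                 sdnn = mean(vapply(reps, `[[`, numeric(1), "sdnn")),
                 rmssd = mean(vapply(reps, `[[`, numeric(1), "rmssd")),
                 n_intervals = sum(vapply(reps, `[[`, numeric(1), "n_intervals"))),
            class = "hrv_report")
}

#' Rank-based AUC of classification scores
#'
#' Mann-Whitney form: the probability that a random positive scores above a
#' random negative, ties counting one half.
#'
#' @param scores Numeric scores (e.g. ensemble R-vote fractions).
#' @param labels Labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"R"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "R") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end evaluation of detections against annotations
#'
#' @param detected Detected R sample indices.
#' @param annotated Annotated R sample indices.
#' @param fs Sampling rate, Hz.
#' @param tolerance_s Matching tolerance, seconds.
#' @return List with `counts`, `metrics`, and `hrv` computed from the
#'   detected locations (`NULL` with fewer than 2 detections).
#' @export
evaluate_detections <- function(detected, annotated, fs, tolerance_s = 0.15) {
  counts <- match_detections(detected, annotated, fs, tolerance_s)
  metrics <- suppressWarnings(classification_metrics(counts))
  hrv <- if (length(detected) >= 2) hrv_metrics(detected, fs) else NULL
  list(counts = counts, metrics = metrics, hrv = hrv)
}
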