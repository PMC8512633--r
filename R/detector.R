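# Dataset splitting, the feature-subset decision-tree ensemble, majority
# voting, and R location correction (RLC).

#' Gini impurity of a class-probability vector
#'
#' `1 - sum(p^2)`: 0 for a pure node, approaching 1 with many balanced
#' classes. This is the split criterion used by the ensemble's trees.
#'
#' @param class_probs Non-negative probabilities summing to 1 (tolerance 1e-9).
#' @return Impurity in `[0, 1)`.
#' @examples
#' gini_index(c(0.9, 0.1))  # 0.18
#' @export
gini_index <- function(class_probs) {
  if (any(class_probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("probabilities must sum to 1", call. = FALSE)
  1 - sum(class_probs^2)
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits labelled ROI windows into train/test, stratified by beat type
#' (False-R windows form their own stratum), then assigns the training rows
#' to `cv_folds` folds. Strata with fewer than 2 members go wholly to
#' training with a warning. Deterministic given `seed`.
#'
#' @param strata Character vector: one stratum id per row (e.g. beat type,
#'   with `"False-R"` for negative windows).
#' @param train_frac Training fraction (default 0.8).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return List with integer vectors `train`, `test` (row indices) and
#'   `fold_id` (parallel to `train`).
#' @export
split_dataset <- function(strata, train_frac = 0.8, cv_folds = 10, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, cv_folds >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  strata <- as.character(strata)
  train <- integer()
  test <- integer()
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    if (length(idx) < 2) {
      warning("stratum '", s, "' has fewer than 2 members; placed in training",
              call. = FALSE)
      train <- c(train, idx)
      next
    }
    n_tr <- round(train_frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    tr <- sample(idx, n_tr)
    train <- c(train, tr)
    test <- c(test, setdiff(idx, tr))
  }
  train <- sort(train)
  test <- sort(test)
  fold_id <- sample(rep(seq_len(cv_folds), length.out = length(train)))
  list(train = train, test = test, fold_id = fold_id)
}

all_feature_subsets <- function(features) {
  n <- length(features)
  lapply(seq_len(2^n - 1L), function(mask)
    features[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
}

fit_tree <- function(data, cols) {
  d <- data[, c(cols, "label"), drop = FALSE]
  d$label <- factor(d$label, levels = c("False-R", "R"))
  rpart::rpart(label ~ ., data = d,
               method = "class",
               control = rpart::rpart.control(cp = 0, xval = 0, minsplit = 2,
                                              minbucket = 1, maxdepth = 30))
}

subset_cv_accuracy <- function(data, cols, fold_id) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- data[fold_id != f, , drop = FALSE]
    va <- data[fold_id == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2) {
      pred <- rep(tr$label[1], nrow(va))
    } else {
      pred <- as.character(predict(fit_tree(tr, cols), va, type = "class"))
    }
    correct <- correct + sum(pred == va$label)
  }
  correct / length(fold_id)
}

#' Train the feature-subset decision-tree ensemble
#'
#' Enumerates all `2^n - 1` non-empty subsets of the `n` selected features.
#' For each subset, a decision tree (Gini criterion, unbounded depth) is
#' trained on an independent random 75% sample of the training data
#' restricted to that subset, and its validation accuracy is the mean k-fold
#' cross-validation accuracy over the supplied folds. The `ensemble_size`
#' trees with the highest validation accuracy are kept (ties broken toward
#' larger subsets, then lexicographically).
#'
#' @param train_data Data frame with the feature columns and a `label`
#'   column (`"R"` / `"False-R"`).
#' @param selected Character vector of `n >= 1` selected feature names
#'   (`n <= 16`: the subset enumeration is exponential in `n`; reduce
#'   `max_features` in SFS if this triggers).
#' @param fold_id Integer fold assignment per training row (e.g. from
#'   [split_dataset()]).
#' @param ensemble_size Number of trees kept (default 16).
#' @param sample_frac Per-tree training sample fraction (default 0.75).
#' @param seed Integer seed.
#' @return An object of class `rpeak_ensemble`: `trees` (rpart fits),
#'   `subsets`, `cv_accuracy`, `n_features`.
#' @export
train_ensemble <- function(train_data, selected, fold_id,
                           ensemble_size = 16, sample_frac = 0.75, seed = 1L) {
  n <- length(selected)
  if (n < 1) stop("need at least one selected feature", call. = FALSE)
  if (n > 16)
    stop("n = ", n, " selected features would enumerate 2^n - 1 subsets; ",
         "reduce max_features", call. = FALSE)
  stopifnot(all(selected %in% names(train_data)),
            length(fold_id) == nrow(train_data),
            length(unique(train_data$label)) == 2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  subsets <- all_feature_subsets(selected)
  trees <- vector("list", length(subsets))
  acc <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    cols <- subsets[[i]]
    acc[i] <- subset_cv_accuracy(train_data, cols, fold_id)
    samp <- sample(nrow(train_data), round(sample_frac * nrow(train_data)))
    trees[[i]] <- fit_tree(train_data[samp, , drop = FALSE], cols)
  }

  size <- lengths(subsets)
  key <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  ord <- order(-acc, -size, key)
  keep <- ord[seq_len(min(ensemble_size, length(subsets)))]
  structure(list(trees = trees[keep], subsets = subsets[keep],
                 cv_accuracy = acc[keep], n_features = n,
                 feature_names = selected),
            class = "rpeak_ensemble")
}

#' @export
print.rpeak_ensemble <- function(x, ...) {
  cat(sprintf("<rpeak_ensemble>  %d trees over subsets of %d features\n",
              length(x$trees), x$n_features))
  cat(sprintf("  CV accuracy: %.4f - %.4f\n",
              min(x$cv_accuracy), max(x$cv_accuracy)))
  invisible(x)
}

#' Classify ROI windows by ensemble majority vote
#'
#' Each tree votes on its own feature subset; a window is classified `"R"`
#' when at least `ceiling(n_trees / 2)` trees vote R (so an even ensemble's
#' tie goes to R: missing a beat costs more than a false alarm, which the
#' location-correction stage can still absorb).
#'
#' @param object A trained [train_ensemble()] result.
#' @param newdata Data frame with the feature columns.
#' @param type `"class"` for labels, `"votes"` for the R-vote fraction.
#' @param ... Unused.
#' @return Character vector of labels, or numeric vote fractions.
#' @export
predict.rpeak_ensemble <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  if (nrow(newdata) == 0)
    return(if (type == "class") character() else numeric())
  votes <- vapply(object$trees, function(tr)
    as.character(predict(tr, newdata, type = "class")) == "R",
    logical(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  frac <- rowMeans(votes)
  if (type == "votes") return(frac)
  n_tr <- length(object$trees)
  ifelse(rowSums(votes) >= ceiling(n_tr / 2), "R", "False-R")
}

#' Correct detected R locations on the raw signal
#'
#' Each detection is snapped to the sample of maximum raw-signal amplitude
#' within `half_window` samples on either side (clipped to the record). The
#' default half-window is 4 samples at 360 Hz, rescaled with the sampling
#' rate. Ties resolve to the earliest index. With `absolute = TRUE` the
#' search maximises `|e - median(e)|`, for leads with inverted QRS polarity.
#'
#' @param record An [ecg_record].
#' @param locations Integer vector of detected R sample indices.
#' @param half_window Search half-width in samples (default
#'   `round(4 * fs / 360)`).
#' @param absolute Use magnitude about the signal median instead of raw value.
#' @return Integer vector of corrected locations.
#' @export
rlc_correct <- function(record, locations, half_window = NULL, absolute = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  e <- record$samples
  if (absolute) e <- abs(e - stats::median(e))
  h <- as.integer(half_window %||% max(1, round(4 * record$fs / 360)))
  n <- length(e)
  vapply(as.integer(locations), function(k) {
    stopifnot(k >= 1L, k <= n)
    lo <- max(1L, k - h)
    hi <- min(n, k + h)
    lo + which.max(e[lo:hi]) - 1L
  }, integer(1))
}
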