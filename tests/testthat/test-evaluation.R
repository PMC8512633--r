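test_that("exact and disjoint detections produce the obvious counts", {
  ann <- c(100L, 400L, 700L)
  m <- match_detections(ann, ann, fs = 360)
  expect_identical(c(m$TP, m$FP, m$FN), c(3, 0, 0))

  m2 <- match_detections(c(ann, 2000L), ann, fs = 360)
  expect_identical(c(m2$TP, m2$FP, m2$FN), c(3, 1, 0))

  m3 <- match_detections(integer(), ann, fs = 360)
  expect_identical(c(m3$TP, m3$FP, m3$FN), c(0, 0, 3))
})

test_that("greedy matching equals exhaustive optimal matching on small sets", {
  # brute force: maximum bipartite matching by recursion over detections
  brute_max_matching <- function(det, ann, tol) {
    if (length(det) == 0) return(0L)
    best <- brute_max_matching(det[-1], ann, tol)  # leave det[1] unmatched
    for (j in seq_along(ann)) {
      if (abs(det[1] - ann[j]) <= tol)
        best <- max(best, 1L + brute_max_matching(det[-1], ann[-j], tol))
    }
    best
  }
  set.seed(12)
  fs <- 360
  tol <- round(0.15 * fs)
  for (rep in 1:20) {
    ann <- sort(sample(seq(100, 4000, by = 150), 8))
    keep <- runif(8) < 0.8
    det <- sort(unique(c(ann[keep] + sample(-40:40, sum(keep), replace = TRUE),
                         sample(1:4000, 2))))
    m <- match_detections(det, ann, fs)
    expect_identical(as.integer(m$TP), brute_max_matching(det, ann, tol))
  }
})

test_that("matching is invariant under a global time shift", {
  set.seed(3)
  ann <- sort(sample(1000:8000, 12))
  det <- sort(ann + sample(-30:30, 12, TRUE))
  m1 <- match_detections(det, ann, fs = 360)
  m2 <- match_detections(det + 500L, ann + 500L, fs = 360)
  expect_identical(c(m1$TP, m1$FP, m1$FN), c(m2$TP, m2$FP, m2$FN))
})

test_that("classification metrics implement the printed forms", {
  m <- suppressWarnings(classification_metrics(confusion_counts(10, 0, 5, 0)))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$der, 0)
  expect_equal(m$accuracy, 100)
  expect_equal(m$recall, 100 * 10 / 15)
  expect_equal(m$specificity, 100)

  und <- suppressWarnings(classification_metrics(confusion_counts(0, 0, 0, 0)))
  expect_true(is.nan(und$sensitivity))
  w <- capture_warnings(classification_metrics(confusion_counts(0, 1, 0, 1)))
  expect_true(any(grepl("DER", w)))
})

test_that("HRV statistics match their divisor conventions and a loop oracle", {
  fs <- 360
  # constant 0.8 s intervals
  locs <- cumsum(c(1, rep(0.8 * fs, 10)))
  h <- hrv_metrics(locs, fs)
  expect_equal(h$mrr, 0.8)
  expect_equal(h$sdnn, 0)
  expect_equal(h$rmssd, 0)

  # intervals 0.8 and 1.0 s
  h2 <- hrv_metrics(c(0, 0.8, 1.8) * fs + 1, fs)
  expect_equal(h2$mrr, 0.9)
  expect_equal(h2$sdnn, 0.1)

  # naive-loop oracle over 100 random intervals
  set.seed(77)
  rr <- runif(100, 0.6, 1.1)
  locs3 <- cumsum(c(1, round(rr * fs)))
  h3 <- hrv_metrics(locs3, fs)
  iv <- numeric(); for (i in 2:length(locs3)) iv <- c(iv, (locs3[i] - locs3[i - 1]) / fs)
  mrr_o <- 0; for (v in iv) mrr_o <- mrr_o + v / length(iv)
  sd_o <- 0; for (v in iv) sd_o <- sd_o + (v - mrr_o)^2
  sd_o <- sqrt(sd_o / length(iv))
  rm_o <- 0; for (i in 2:length(iv)) rm_o <- rm_o + (iv[i] - iv[i - 1])^2
  rm_o <- sqrt(rm_o / (length(iv) - 1))
  expect_equal(h3$mrr, mrr_o)
  expect_equal(h3$sdnn, sd_o)
  expect_equal(h3$rmssd, rm_o)

  expect_error(hrv_metrics(100L, fs), "at least 2")
})

test_that("pooled and per-record HRV aggregation both work", {
  fs <- 360
  l1 <- cumsum(c(1, rep(0.8 * fs, 5)))
  l2 <- cumsum(c(1, rep(1.0 * fs, 5)))
  pooled <- aggregate_hrv(list(l1, l2), fs, mode = "pooled")
  expect_equal(pooled$mrr, 0.9)
  per <- aggregate_hrv(list(l1, l2), fs, mode = "mean")
  expect_equal(per$mrr, 0.9)
  expect_equal(per$sdnn, 0)
  expect_gt(pooled$sdnn, 0)
})

test_that("rank AUC equals the all-pairs oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c("R", "R", "False-R", "False-R")), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c("R", "False-R"), 3)), 0.5)

  set.seed(5)
  scores <- round(runif(20), 2)  # duplicates force tie handling
  labels <- sample(c("R", "False-R"), 20, TRUE)
  pos <- scores[labels == "R"]; neg <- scores[labels != "R"]
  acc <- 0
  for (p in pos) for (q in neg) acc <- acc + (p > q) + 0.5 * (p == q)
  expect_equal(auc_score(scores, labels), acc / (length(pos) * length(neg)))

  expect_error(auc_score(1:3, rep("R", 3)), "both classes")
})
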