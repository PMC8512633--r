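# helpers: trees whose vote on newdata(a = 1, b = 1) is fixed by construction —
# tree_r splits on `a` toward R, tree_f splits on `b` toward False-R
tree_voting_r <- function() {
  d <- data.frame(a = rep(c(0, 1), each = 10),
                  label = rep(c("False-R", "R"), each = 10))
  qrsdetect:::fit_tree(d, "a")
}
tree_voting_f <- function() {
  d <- data.frame(b = rep(c(0, 1), each = 10),
                  label = rep(c("R", "False-R"), each = 10))
  qrsdetect:::fit_tree(d, "b")
}

test_that("gini index matches the closed form and validates input", {
  expect_equal(gini_index(1), 0)
  expect_equal(gini_index(c(0.5, 0.5)), 0.5)
  expect_equal(gini_index(c(0.9, 0.1)), 0.18)
  expect_error(gini_index(c(-0.1, 1.1)), "non-negative")
  expect_error(gini_index(c(0.5, 0.4)), "sum to 1")
})

test_that("stratified splitting honours fractions, strata and the seed", {
  s <- split_dataset(rep("N", 100), seed = 1)
  expect_identical(length(s$train), 80L)
  expect_identical(length(s$test), 20L)
  expect_identical(sort(c(s$train, s$test)), 1:100)
  expect_identical(sort(unique(s$fold_id)), 1:10)

  strata <- rep(c("N", "V"), each = 10)
  s2 <- split_dataset(strata, seed = 2)
  for (g in c("N", "V")) {
    expect_identical(sum(strata[s2$train] == g), 8L)
    expect_identical(sum(strata[s2$test] == g), 2L)
  }

  expect_identical(split_dataset(rep(c("a", "b"), 50), seed = 7),
                   split_dataset(rep(c("a", "b"), 50), seed = 7))

  expect_warning(s3 <- split_dataset(c(rep("N", 10), "Q"), seed = 1),
                 "fewer than 2")
  expect_true(which(c(rep("N", 10), "Q") == "Q") %in% s3$train)
})

test_that("the ensemble enumerates 2^n - 1 feature subsets", {
  d <- make_separable_features(n = 80)
  fold <- rep(1:10, length.out = 80)
  # n = 4 features -> 15 trees when the cap allows
  e4 <- train_ensemble(d, c("good", "dup", "noise1", "noise2"), fold,
                       ensemble_size = 100, seed = 1)
  expect_identical(length(e4$trees), 15L)
  expect_identical(length(unique(vapply(e4$subsets, paste, character(1),
                                        collapse = ","))), 15L)
  # n = 3 with ensemble_size 16 keeps all 7
  e3 <- train_ensemble(d, c("good", "noise1", "noise2"), fold,
                       ensemble_size = 16, seed = 1)
  expect_identical(length(e3$trees), 7L)
  expect_error(train_ensemble(d, sprintf("f%02d", 1:17), fold), "2\\^n")
})

test_that("subsets containing the separating feature reach perfect CV accuracy", {
  d <- make_separable_features(n = 100)
  fold <- rep(1:10, length.out = 100)
  e <- train_ensemble(d, c("good", "noise1"), fold, ensemble_size = 3, seed = 2)
  has_good <- vapply(e$subsets, function(s) "good" %in% s, logical(1))
  expect_true(all(e$cv_accuracy[has_good] == 1))
  expect_true(all(e$cv_accuracy[!has_good] < 1))
})

test_that("majority voting follows the tie-toward-R rule", {
  make_ens <- function(n_r, n_total) {
    trees <- c(replicate(n_r, tree_voting_r(), simplify = FALSE),
               replicate(n_total - n_r, tree_voting_f(), simplify = FALSE))
    structure(list(trees = trees, subsets = as.list(rep(c("a", "b"),
                                                        c(n_r, n_total - n_r))),
                   cv_accuracy = rep(1, n_total), n_features = 2,
                   feature_names = c("a", "b")),
              class = "rpeak_ensemble")
  }
  nd <- data.frame(a = c(1, 1), b = c(1, 1))
  expect_identical(predict(make_ens(9, 16), nd), c("R", "R"))
  expect_identical(predict(make_ens(8, 16), nd), c("R", "R"))     # even tie -> R
  expect_identical(predict(make_ens(7, 16), nd), c("False-R", "False-R"))
  expect_identical(predict(make_ens(0, 16), nd), c("False-R", "False-R"))
  expect_equal(predict(make_ens(8, 16), nd, type = "votes"), c(0.5, 0.5))
})

test_that("a single-tree ensemble reduces to that tree", {
  d <- make_separable_features(n = 80)
  fold <- rep(1:10, length.out = 80)
  e1 <- train_ensemble(d, "good", fold, seed = 3)
  expect_identical(length(e1$trees), 1L)
  nd <- d[sample(80, 20), ]
  expect_identical(predict(e1, nd),
                   as.character(predict(e1$trees[[1]], nd, type = "class")))
})

test_that("retraining with the same seed reproduces trees and votes", {
  d <- make_separable_features(n = 90)
  d$good <- d$good + rnorm(90, 0, 0.3)
  fold <- rep(1:10, length.out = 90)
  a <- train_ensemble(d, c("good", "noise1", "noise2"), fold, seed = 11)
  b <- train_ensemble(d, c("good", "noise1", "noise2"), fold, seed = 11)
  expect_identical(a$subsets, b$subsets)
  expect_identical(a$cv_accuracy, b$cv_accuracy)
  expect_identical(predict(a, d), predict(b, d))
})

test_that("RLC snaps to the neighbourhood maximum with bounded movement", {
  x <- numeric(100); x[53] <- 1; x[90] <- 2
  rec <- ecg_record(x, fs = 360)
  h <- round(4 * 360 / 360)
  expect_identical(rlc_correct(rec, 50L), 53L)     # max at k+3
  expect_identical(rlc_correct(rec, 53L), 53L)     # already at the max
  expect_identical(rlc_correct(rec, 2L), which.max(x[1:6]))  # clipped at start

  # ties resolve to the earliest index
  xt <- numeric(50); xt[c(20, 22)] <- 1
  expect_identical(rlc_correct(ecg_record(xt, 360), 21L), 20L)

  # invariants: bounded movement, never-decreasing amplitude
  set.seed(19)
  xs <- rnorm(2000)
  recs <- ecg_record(xs, 360)
  ks <- sample(5:1995, 50)
  corr <- rlc_correct(recs, ks)
  expect_true(all(abs(corr - ks) <= h))
  expect_true(all(xs[corr] >= xs[ks]))

  # inverted-polarity search
  xi <- numeric(100); xi[40] <- -3
  expect_identical(rlc_correct(ecg_record(xi, 360), 38L, absolute = TRUE), 40L)
})
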