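test_that("window statistics match the stated population formulas", {
  comp <- make_component(Re = c(1, 2, 3), Rw = c(9, 10, 11), Rn = c(1, 1, 1))
  f <- extract_features(make_window(1, 3, loc = 2), comp)
  expect_equal(f$FmuE, 2)
  expect_equal(f$FsdE, sqrt(2 / 3))
  expect_equal(f$FrmsE, sqrt(14 / 3))
  expect_equal(f$FpowE, 14 / 3)
  expect_equal(f$FareaE, 6)
  expect_equal(f$FsnrE, 2 / sqrt(2 / 3))
  expect_equal(f$FsnrS, 6 / 3)
  expect_equal(f$FhP, comp$Re[2])
  expect_equal(f$FfP, comp$Rw[2])

  # deviations symmetric about the mean give zero skewness
  expect_equal(f$FskewE, 0)
})

test_that("degenerate constant windows hit the capping rules", {
  f <- extract_features(make_window(1, 4, loc = 2),
                        make_component(Re = rep(2, 4), Rn = rep(0, 4)))
  expect_equal(f$FsdE, 0)
  expect_equal(f$FsnrE, 1e6)   # sigma = 0 sentinel
  expect_equal(f$FkurtE, 0)
  expect_equal(f$FskewE, 0)
  expect_equal(f$FentE, 0)     # constant window entropy
  expect_equal(f$FsnrS, 1e6)   # zero noise in the window
  expect_true(all(is.finite(as.numeric(f[qrsdetect:::FEATURE_NAMES]))))
})

test_that("each feature equals a naive-loop oracle on a random window", {
  set.seed(31)
  n <- 64
  Re <- abs(rnorm(n)); Rw <- runif(n, 5, 25); Rn <- abs(rnorm(n, 0, 0.2))
  comp <- make_component(Re, Rw, Rn)
  win <- make_window(1, n, loc = 17, width = 9.5)
  f <- extract_features(win, comp)

  loop_stats <- function(x) {
    N <- length(x)
    mu <- 0; for (v in x) mu <- mu + v / N
    s2 <- 0; for (v in x) s2 <- s2 + (v - mu)^2
    sigma <- sqrt(s2 / N)
    sq <- 0; for (v in x) sq <- sq + v^2
    a <- 0; for (v in x) a <- a + v
    sh <- x - min(x); p <- sh / sum(sh)
    H <- 0; for (q in p) if (q > 0) H <- H - q * log(q)
    k4 <- 0; k3 <- 0
    for (v in x) { k4 <- k4 + (v - mu)^4; k3 <- k3 + (v - mu)^3 }
    list(mu = mu, sd = sigma, snr = mu / sigma, rms = sqrt(sq / N),
         pow = sq / N, area = a, ent = H,
         kurt = k4 / ((N - 1) * sigma^4), skew = k3 / ((N - 1) * sigma^3))
  }
  oe <- loop_stats(Re); of <- loop_stats(Rw)
  expect_equal(f$FmuE, oe$mu);    expect_equal(f$FmuF, of$mu)
  expect_equal(f$FsdE, oe$sd);    expect_equal(f$FsdF, of$sd)
  expect_equal(f$FsnrE, oe$snr);  expect_equal(f$FsnrF, of$snr)
  expect_equal(f$FrmsE, oe$rms);  expect_equal(f$FrmsF, of$rms)
  expect_equal(f$FpowE, oe$pow);  expect_equal(f$FpowF, of$pow)
  expect_equal(f$FareaE, oe$area); expect_equal(f$FareaF, of$area)
  expect_equal(f$FentE, oe$ent);  expect_equal(f$FentF, of$ent)
  expect_equal(f$FkurtE, oe$kurt); expect_equal(f$FkurtF, of$kurt)
  expect_equal(f$FskewE, oe$skew); expect_equal(f$FskewF, of$skew)
  expect_equal(f$FsnrS, sum(Re) / sum(Rn))
  expect_equal(f$FpP, win$prominence)
  expect_equal(f$FwP, win$width)
})

test_that("inter-peak distances use neighbours and the median at edges", {
  n <- 600
  comp <- make_component(abs(rnorm(n)))
  w <- rbind(make_window(95, 105, loc = 100), make_window(295, 305, loc = 300),
             make_window(515, 525, loc = 520))
  f <- extract_features(w, comp)
  expect_equal(f$FpD, c(210, 200, 220))  # median gap 210 substituted at the left edge
  expect_equal(f$FfD, c(200, 220, 210))
})

test_that("feature extraction is shift-equivariant", {
  set.seed(4)
  n <- 400; s <- 37
  Re <- abs(rnorm(n)); Rw <- runif(n, 5, 25); Rn <- abs(rnorm(n))
  w <- rbind(make_window(50, 60, loc = 55), make_window(150, 160, loc = 155))
  f1 <- extract_features(w, make_component(Re, Rw, Rn))
  w2 <- w; w2$start <- w$start + s; w2$end <- w$end + s; w2$location <- w$location + s
  f2 <- extract_features(w2, make_component(c(rep(0, s), Re), c(rep(10, s), Rw),
                                            c(rep(0.1, s), Rn)))
  nm <- qrsdetect:::FEATURE_NAMES
  expect_equal(as.numeric(f1[1, nm]), as.numeric(f2[1, nm]))
  expect_equal(as.numeric(f1[2, nm]), as.numeric(f2[2, nm]))
})

test_that("SFS picks a perfectly separating feature first with zero MSE", {
  d <- make_separable_features()
  res <- sfs_select(d, candidates = c("good", "noise1", "noise2"), seed = 3)
  expect_identical(res$selected[1], "good")
  expect_equal(res$mse[1], 0)

  # exhaustive single-feature sweep oracle
  set.seed(3)
  fold <- sample(rep(1:5, length.out = nrow(d)))
  sweep <- vapply(c("good", "noise1", "noise2"), function(f)
    qrsdetect:::wrapper_cv_mse(d, f, fold), numeric(1))
  expect_identical(names(which.min(sweep)), "good")
})

test_that("a duplicated feature is never added and the trajectory is monotone", {
  d <- make_separable_features(n = 120)
  d$good <- d$good + rnorm(120, 0, 0.35)   # keep separation imperfect
  d$dup <- d$good
  res <- sfs_select(d, candidates = c("good", "dup", "noise1", "noise2"),
                    max_features = 4, seed = 5)
  expect_false("dup" %in% res$selected && "good" %in% res$selected)
  expect_true(all(diff(res$mse) <= 0))

  one <- sfs_select(d, candidates = c("good", "noise1"), max_features = 1, seed = 5)
  expect_identical(length(one$selected), 1L)
})

test_that("single-class datasets are rejected", {
  d <- make_separable_features()
  d$label <- "R"
  expect_error(sfs_select(d, candidates = "good"), "both classes")
})
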