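test_that("simple peak geometries are found with correct descriptors", {
  # single triangular bump
  tri <- c(rep(0, 5), 1:5, 4:1, rep(0, 5))
  pk <- find_energy_peaks(tri, min_prominence_frac = 0.5)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$location, 10L)
  expect_equal(pk$height, 5)
  expect_equal(pk$prominence, 5)

  # two equal bumps separated by a zero valley
  two <- c(0, 1, 3, 1, 0, 0, 1, 3, 1, 0)
  pk2 <- find_energy_peaks(two, min_prominence_frac = 0.5)
  expect_identical(pk2$location, c(3L, 8L))
  expect_equal(pk2$height, c(3, 3))

  # flat zero series yields nothing
  expect_identical(nrow(find_energy_peaks(numeric(100))), 0L)
})

test_that("peak set matches an exhaustive local-maximum oracle", {
  set.seed(14)
  rec <- generate_ecg(synth_config(duration = 20, mean_hr = 70, seed = 14,
                                   white_noise_sd = 0.003))
  comp <- suppressWarnings(qrs_component(rec))
  x <- comp$Re
  frac <- 1e-4
  pk <- find_energy_peaks(comp, min_prominence_frac = frac)

  # brute force: strict local maxima, prominence by full scans
  oracle <- integer()
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) {
      l <- i; while (l > 1 && x[l - 1] <= x[i]) l <- l - 1
      r <- i; while (r < length(x) && x[r + 1] <= x[i]) r <- r + 1
      prom <- x[i] - max(min(x[l:i]), min(x[i:r]))
      if (prom >= frac * max(x)) oracle <- c(oracle, i)
    }
  }
  expect_identical(pk$location, oracle)
})

test_that("adaptive windows follow the half-width arithmetic", {
  pk <- data.frame(location = 101L, height = 1, prominence = 1, width = 10)
  w <- aws_windows(pk, 1000L)
  expect_identical(w$start, 96L)   # covers 11 samples centred on the peak
  expect_identical(w$end, 106L)

  # odd width floors the half-width
  w7 <- aws_windows(data.frame(location = 101L, height = 1, prominence = 1,
                               width = 7), 1000L)
  expect_identical(c(w7$start, w7$end), c(98L, 104L))

  # clipping at the record start
  wc <- aws_windows(data.frame(location = 4L, height = 1, prominence = 1,
                               width = 10), 1000L)
  expect_identical(wc$start, 1L)
  expect_identical(wc$end, 9L)

  # minimum half-width of one sample
  w1 <- aws_windows(data.frame(location = 50L, height = 1, prominence = 1,
                               width = 1.2), 1000L)
  expect_identical(c(w1$start, w1$end), c(49L, 51L))
})

test_that("windows stay in bounds and contain their peaks", {
  rec <- generate_ecg(synth_config(duration = 15, seed = 2, white_noise_sd = 0.005))
  comp <- suppressWarnings(qrs_component(rec))
  pk <- find_energy_peaks(comp)
  w <- aws_windows(pk, length(comp$Re))
  expect_true(all(w$start >= 1 & w$end <= length(comp$Re)))
  expect_true(all(w$location >= w$start & w$location <= w$end))
})

test_that("window labels agree with a brute-force containment oracle", {
  fs <- 360
  tol <- round(0.05 * fs)
  w <- make_window(95, 106, loc = 100)
  expect_identical(label_windows(w, data.frame(sample = 100, type = "N"), fs)$label, "R")
  expect_identical(label_windows(w, data.frame(sample = 300, type = "N"), fs)$label, "False-R")

  set.seed(8)
  starts <- sort(sample(1:5000, 50))
  wins <- data.frame(start = starts, end = starts + sample(3:20, 50, TRUE))
  wins$location <- (wins$start + wins$end) %/% 2
  wins$height <- 1; wins$prominence <- 1; wins$width <- wins$end - wins$start
  ann <- data.frame(sample = sort(sample(1:5200, 40)), type = "N")
  lab <- label_windows(wins, ann, fs)$label
  oracle <- vapply(seq_len(nrow(wins)), function(i)
    if (any(ann$sample >= wins$start[i] - tol & ann$sample <= wins$end[i] + tol))
      "R" else "False-R", character(1))
  expect_identical(lab, oracle)
})

test_that("every clean-record beat falls in exactly one R-labelled window", {
  rec <- generate_ecg(synth_config(duration = 20, mean_hr = 65, seed = 9))
  comp <- suppressWarnings(qrs_component(rec))
  pk <- find_energy_peaks(comp, min_prominence_frac = 0.01)
  w <- label_windows(aws_windows(pk, length(comp$Re)), rec$annotations, rec$fs)
  tol <- round(0.05 * rec$fs)
  hits <- vapply(rec$annotations$sample, function(s)
    sum(s >= w$start[w$label == "R"] - tol & s <= w$end[w$label == "R"] + tol),
    numeric(1))
  expect_true(all(hits == 1))
})
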