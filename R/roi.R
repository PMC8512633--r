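# Adaptive window sizing (AWS): local peaks of the in-band energy seed
# candidate windows half a peak-width wide on each side of the peak.

# Plateau-aware local maxima: returns the midpoint index of each maximal run
# strictly higher than both neighbouring distinct values.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i])
        peaks <- c(peaks, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

# Topographic prominence of peak p: scan each side until a strictly higher
# sample (or the signal edge); the key saddle is the higher of the two
# interval minima.
peak_prominence <- function(x, p) {
  h <- x[p]
  i <- p
  left_min <- h
  while (i > 1L && x[i - 1L] <= h) {
    i <- i - 1L
    if (x[i] < left_min) left_min <- x[i]
  }
  i <- p
  right_min <- h
  n <- length(x)
  while (i < n && x[i + 1L] <= h) {
    i <- i + 1L
    if (x[i] < right_min) right_min <- x[i]
  }
  h - max(left_min, right_min)
}

# Width (in samples, fractional) at half prominence, crossings linearly
# interpolated; clipped at the signal edges.
peak_width <- function(x, p, prominence) {
  ref <- x[p] - prominence / 2
  n <- length(x)
  i <- p
  while (i > 1L && x[i - 1L] > ref) i <- i - 1L
  left <- if (i == 1L || x[i] == ref) as.numeric(i)
          else i - (x[i] - ref) / (x[i] - x[i - 1L])
  i <- p
  while (i < n && x[i + 1L] > ref) i <- i + 1L
  right <- if (i == n || x[i] == ref) as.numeric(i)
           else i + (x[i] - ref) / (x[i] - x[i + 1L])
  max(right - left, 1e-9)
}

#' Find local peaks of the in-band energy series
#'
#' Detects all local maxima of `Re` with topographic prominence at least
#' `min_prominence_frac` of the series maximum, and measures each peak's
#' height, prominence and width at half prominence. The default fraction is
#' deliberately permissive: the peak stage must under-filter (P/T and noise
#' peaks are rejected later by the classifier).
#'
#' @param component A `qrs_component` (see [dmse_aggregate()]), or a numeric
#'   energy series.
#' @param min_prominence_frac Minimum prominence as a fraction of `max(Re)`.
#' @return Data frame with columns `location` (1-based sample index),
#'   `height`, `prominence`, `width` (samples), sorted by location.
#' @export
find_energy_peaks <- function(component, min_prominence_frac = 1e-4) {
  x <- if (inherits(component, "qrs_component")) component$Re else as.numeric(component)
  empty <- data.frame(location = integer(), height = numeric(),
                      prominence = numeric(), width = numeric())
  if (length(x) == 0 || max(x) <= 0) return(empty)
  locs <- local_maxima(x)
  if (length(locs) == 0) return(empty)
  prom <- vapply(locs, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence_frac * max(x)
  locs <- locs[keep]; prom <- prom[keep]
  if (length(locs) == 0) return(empty)
  wid <- vapply(seq_along(locs), function(i) peak_width(x, locs[i], prom[i]), numeric(1))
  data.frame(location = locs, height = x[locs], prominence = prom, width = wid)
}

#' Build adaptive ROI windows around energy peaks
#'
#' Each window spans half the peak's width on each side of the peak:
#' `QRSW = max(floor(width / 2), 1)`, window `[location - QRSW,
#' location + QRSW]` (inclusive), clipped to the signal.
#'
#' @param peaks Data frame from [find_energy_peaks()].
#' @param signal_length Length of the underlying series.
#' @return Data frame with columns `start`, `end` (1-based inclusive),
#'   `location`, `height`, `prominence`, `width`.
#' @export
aws_windows <- function(peaks, signal_length) {
  if (nrow(peaks) == 0)
    return(data.frame(start = integer(), end = integer(), location = integer(),
                      height = numeric(), prominence = numeric(), width = numeric()))
  qrsw <- pmax(as.integer(floor(peaks$width / 2)), 1L)
  data.frame(start = pmax(as.integer(peaks$location) - qrsw, 1L),
             end = pmin(as.integer(peaks$location) + qrsw, as.integer(signal_length)),
             location = peaks$location, height = peaks$height,
             prominence = peaks$prominence, width = peaks$width)
}

#' Label ROI windows against beat annotations
#'
#' A window is labelled `"R"` when at least one annotated beat falls inside
#' it after dilating both ends by `round(tolerance_s * fs)` samples (the
#' decomposition shifts energy peaks slightly relative to the raw-signal R
#' apex), otherwise `"False-R"`. The beat type of the nearest contained
#' annotation is recorded for stratified splitting.
#'
#' @param windows Data frame from [aws_windows()].
#' @param annotations Annotation data frame (`sample`, `type`).
#' @param fs Sampling rate, Hz.
#' @param tolerance_s Dilation on each side, seconds (default 0.05).
#' @return `windows` with added columns `label` and `beat_type` (`NA` for
#'   False-R windows).
#' @export
label_windows <- function(windows, annotations, fs, tolerance_s = 0.05) {
  tol <- round(tolerance_s * fs)
  n <- nrow(windows)
  label <- rep("False-R", n)
  beat_type <- rep(NA_character_, n)
  if (n > 0 && !is.null(annotations) && nrow(annotations) > 0) {
    for (i in seq_len(n)) {
      inside <- which(annotations$sample >= windows$start[i] - tol &
                      annotations$sample <= windows$end[i] + tol)
      if (length(inside) > 0) {
        label[i] <- "R"
        nearest <- inside[which.min(abs(annotations$sample[inside] - windows$location[i]))]
        beat_type[i] <- annotations$type[nearest]
      }
    }
  }
  windows$label <- label
  windows$beat_type <- beat_type
  windows
}
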