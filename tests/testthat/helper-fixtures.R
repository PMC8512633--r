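# Shared fixtures, built in code.

# A qrs_component-like object from raw series, for feature/ROI tests.
make_component <- function(Re, Rw = NULL, Rn = NULL, fs = 360) {
  n <- length(Re)
  structure(list(Re = Re,
                 Rw = Rw %||% rep(10, n),
                 Rn = Rn %||% rep(0.1, n),
                 in_band = matrix(TRUE, n, 1), selected = 1L,
                 band = band_config(), fs = fs),
            class = "qrs_component")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A one-row window frame covering samples start:end with its peak at `loc`.
make_window <- function(start, end, loc = NULL, width = end - start + 1) {
  loc <- loc %||% ((start + end) %/% 2)
  data.frame(start = start, end = end, location = loc,
             height = 1, prominence = 1, width = width)
}

# A spectrum stub carrying only the per-mode summaries (for mode selection).
make_spectrum_summary <- function(mu, sd) {
  structure(list(mu_freq = mu, sd_freq = sd), class = "hilbert_spectrum")
}

# A full spectrum stub with given inst_freq / inst_energy matrices.
make_spectrum <- function(inst_freq, inst_energy, fs = 360) {
  structure(list(inst_freq = inst_freq, inst_energy = inst_energy,
                 amplitude = sqrt(inst_energy), phase = inst_freq * 0,
                 mu_freq = colMeans(inst_freq),
                 sd_freq = apply(inst_freq, 2, function(c) sqrt(mean((c - mean(c))^2))),
                 fs = fs),
            class = "hilbert_spectrum")
}

# A small two-class feature set: `good` separates the classes perfectly,
# the remaining columns are noise (one of them duplicates `good`).
make_separable_features <- function(n = 60, seed = 7) {
  set.seed(seed)
  label <- rep(c("R", "False-R"), length.out = n)
  good <- ifelse(label == "R", 1, 0) + runif(n, -0.2, 0.2)
  data.frame(good = good, dup = good, noise1 = rnorm(n), noise2 = rnorm(n),
             label = label, stringsAsFactors = FALSE)
}

# DFT-peak frequency oracle (Hz): location of the periodogram maximum.
dft_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(n %/% 2)                       # skip DC
  ((half - 1) / n * fs)[which.max(p[half])]
}
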