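# ECG record container plus WFDB and CSV readers/writers.
#
# Conventions used throughout the package: sample indices are 1-based (R
# idiom; WFDB's 0-based indices are shifted on read/write) and windows are
# inclusive integer ranges [start, end].

# The 18 WFDB beat-annotation codes (QRS-bearing annotation types).
WFDB_BEAT_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "B" = 25L, "e" = 34L, "n" = 35L, "f" = 38L, "r" = 41L
)

#' Construct a single-lead ECG record
#'
#' The canonical container for one ECG lead: a numeric sample vector in mV,
#' its sampling rate, and optional beat annotations (R-peak locations with a
#' beat-type symbol). Synthetic ground truth uses the sentinel type `"N"`.
#'
#' @param samples Numeric vector of signal samples, in millivolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param name Record identifier.
#' @param annotations `NULL`, or a data frame with columns `sample` (1-based
#'   sample indices, strictly increasing, within the record) and `type`
#'   (beat-type symbol).
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1 / 360)), fs = 360)
#' rec
#' @export
ecg_record <- function(samples, fs, name = "record", annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("`samples` must contain at least one value", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!all(c("sample", "type") %in% names(annotations)))
      stop("`annotations` needs columns `sample` and `type`", call. = FALSE)
    annotations$sample <- as.integer(annotations$sample)
    annotations$type <- as.character(annotations$type)
    if (nrow(annotations) > 0) {
      if (any(annotations$sample < 1L | annotations$sample > length(samples)))
        stop("annotation sample indices must lie within the record", call. = FALSE)
      if (any(diff(annotations$sample) <= 0L))
        stop("annotation sample indices must be strictly increasing", call. = FALSE)
    }
    rownames(annotations) <- NULL
  }
  structure(
    list(samples = samples, fs = fs, name = as.character(name),
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.1f s)\n",
              x$name, length(x$samples), x$fs, dur))
  n_ann <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  cat(sprintf("  beat annotations: %d\n", n_ann))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, detections = NULL, xlim = NULL, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "mV",
                 main = x$name, xlim = xlim, ...)
  if (!is.null(x$annotations) && nrow(x$annotations) > 0)
    graphics::points((x$annotations$sample - 1) / x$fs,
                     x$samples[x$annotations$sample], col = "blue", pch = 3)
  if (!is.null(detections))
    graphics::points((detections - 1) / x$fs, x$samples[detections],
                     col = "red", pch = 8)
  invisible(x)
}

#' Read an ECG record from CSV
#'
#' Expects one numeric sample per row (in mV). An optional first line
#' `fs=<Hz>` carries the sampling rate; otherwise `fs` must be supplied.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz; overridden by an `fs=` header line if present.
#' @param name Record identifier (defaults to the file name).
#' @return An [ecg_record] without annotations.
#' @export
read_ecg_csv <- function(path, fs = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty CSV file: ", path, call. = FALSE)
  if (grepl("^\\s*fs\\s*=", lines[1])) {
    fs <- as.numeric(sub("^\\s*fs\\s*=\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  if (is.null(fs)) stop("no sampling rate: pass `fs` or use an `fs=<Hz>` header", call. = FALSE)
  if (length(lines) == 0) stop("CSV has a header but no samples: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value at data row %d: '%s'", bad, lines[bad]), call. = FALSE)
  }
  ecg_record(vals, fs = fs, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an ECG record to CSV
#'
#' Writes an `fs=<Hz>` header line followed by one sample per row.
#' Annotations, if present, can be written alongside as a two-column CSV
#' (`sample,type`).
#'
#' @param record An [ecg_record].
#' @param path Output path for the signal.
#' @param ann_path Optional output path for annotations.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, ann_path = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  writeLines(c(sprintf("fs=%.10g", record$fs),
               format(record$samples, digits = 15, trim = TRUE, scientific = FALSE)),
             path)
  if (!is.null(ann_path)) {
    ann <- record$annotations
    if (is.null(ann)) ann <- data.frame(sample = integer(), type = character())
    utils::write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read beat annotations from CSV
#'
#' Companion to [write_ecg_csv()]: a two-column CSV `sample,type`.
#'
#' @param path File path.
#' @return Data frame with columns `sample` (integer) and `type` (character).
#' @export
read_ann_csv <- function(path) {
  ann <- utils::read.csv(path, colClasses = c("integer", "character"))
  names(ann) <- c("sample", "type")
  ann
}

# ---- WFDB -------------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("malformed WFDB header: ", hea_path, call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 2) stop("malformed WFDB header line: ", lines[1], call. = FALSE)
  nsig <- suppressWarnings(as.integer(top[2]))
  fs <- if (length(top) >= 3) suppressWarnings(as.numeric(sub("/.*", "", top[3]))) else 250
  nsamp <- if (length(top) >= 4) suppressWarnings(as.numeric(top[4])) else NA
  if (is.na(nsig) || nsig < 1) stop("malformed WFDB header: bad signal count", call. = FALSE)
  if (length(lines) < 1 + nsig) stop("WFDB header lists ", nsig, " signals but has fewer lines", call. = FALSE)
  sig <- lapply(lines[2:(1 + nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2) stop("malformed WFDB signal line: ", ln, call. = FALSE)
    fmt <- as.integer(sub("x.*|:.*|\\+.*", "", f[2]))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- suppressWarnings(as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field))))
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)) else NA
    adczero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(gain) || gain == 0) gain <- 200
    if (is.na(baseline)) baseline <- if (is.na(adczero)) 0 else adczero
    list(file = f[1], format = fmt, gain = gain, baseline = baseline)
  })
  list(name = sub("/.*", "", top[1]), nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_values <- function(dat_path, fmt, n_values) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    n_tri <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n_tri)]), nrow = 3L)
    s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0FL), 8L)
    s2 <- b[3, ] + bitwShiftL(bitwShiftR(b[2, ], 4L), 8L)
    v <- as.vector(rbind(s1, s2))
    v <- ifelse(v > 2047L, v - 4096L, v)  # 12-bit two's complement
  } else {
    stop("unsupported WFDB .dat format: ", fmt, call. = FALSE)
  }
  if (!is.na(n_values) && length(v) >= n_values) v <- v[seq_len(n_values)]
  v
}

#' Read a WFDB record (header + signal + beat annotations)
#'
#' Minimal reader for the PhysioNet WFDB format: `.hea` headers, `.dat`
#' signals in formats 212 and 16, and `.atr` annotations in the MIT coding.
#' Only beat annotations (the 18 QRS-bearing WFDB annotation codes) are kept;
#' rhythm, signal-quality and other non-beat annotations are dropped. ADC
#' units are converted to mV using the header gain and baseline.
#'
#' @param path Record path without extension (e.g. `"mitdb/100"`), or the
#'   `.hea` path.
#' @param channel 1-based signal channel to extract (default 1, the first lead).
#' @param annotator Annotation file extension (default `"atr"`); `NULL` skips
#'   annotations even if a file exists.
#' @return An [ecg_record]; annotation indices are converted to 1-based.
#' @export
read_wfdb <- function(path, channel = 1L, annotator = "atr") {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  hdr <- parse_wfdb_header(hea)
  if (channel < 1L || channel > hdr$nsig)
    stop("channel ", channel, " out of range (record has ", hdr$nsig, " signals)", call. = FALSE)
  sig <- hdr$signals[[channel]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat, call. = FALSE)
  # all channels in one .dat file are interleaved sample frames
  same_file <- vapply(hdr$signals, function(s) identical(s$file, sig$file), logical(1))
  n_in_file <- sum(same_file)
  n_values <- if (is.na(hdr$nsamp)) NA else hdr$nsamp * n_in_file
  vals <- read_dat_values(dat, sig$format, n_values)
  lane <- which(which(same_file) == channel)
  adc <- vals[seq(lane, length(vals), by = n_in_file)]
  mv <- (adc - sig$baseline) / sig$gain

  ann <- NULL
  if (!is.null(annotator)) {
    atr <- paste0(base, ".", annotator)
    if (file.exists(atr)) ann <- read_wfdb_annotations(atr, n_samples = length(mv))
  }
  ecg_record(mv, fs = hdr$fs, name = basename(base), annotations = ann)
}

#' Read a WFDB annotation file, keeping beat annotations only
#'
#' @param path `.atr` (or other annotator) file path.
#' @param n_samples If given, annotations beyond the record length are dropped.
#' @return Data frame with 1-based `sample` and `type` (WFDB beat symbol).
#' @export
read_wfdb_annotations <- function(path, n_samples = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  words <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  i <- 1L; t <- 0L
  samp <- integer(); code <- integer()
  while (i <= length(words)) {
    w <- words[i]
    cd <- bitwShiftR(w, 10L)
    inc <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (cd == 59L) {          # SKIP: next two words hold a 4-byte increment
      if (i + 2L > length(words)) break
      t <- t + bitwShiftL(words[i + 1L], 16L) + words[i + 2L]
      i <- i + 3L
      next
    } else if (cd %in% c(60L, 61L, 62L)) {  # NUM/SUB/CHN: field setters
      i <- i + 1L
      next
    } else if (cd == 63L) {   # AUX: skip payload (padded to even length)
      i <- i + 1L + as.integer(ceiling(inc / 2))
      next
    }
    t <- t + inc
    samp <- c(samp, t)
    code <- c(code, cd)
    i <- i + 1L
  }
  keep <- code %in% WFDB_BEAT_CODES
  samp <- samp[keep] + 1L   # 0-based on disk -> 1-based
  code <- code[keep]
  if (!is.null(n_samples)) {
    ok <- samp >= 1L & samp <= n_samples
    samp <- samp[ok]; code <- code[ok]
  }
  data.frame(sample = samp,
             type = names(WFDB_BEAT_CODES)[match(code, WFDB_BEAT_CODES)],
             stringsAsFactors = FALSE)
}

#' Write an ECG record in WFDB format
#'
#' Writes `.hea`, `.dat` (format 212 or 16) and, when the record carries
#' annotations, a `.atr` file in the MIT annotation coding. Samples are
#' quantised to ADC units with the given gain, so values are preserved to
#' 1/gain mV.
#'
#' @param record An [ecg_record].
#' @param base Output path without extension.
#' @param format `.dat` format: 212 (packed 12-bit) or 16 (int16).
#' @param gain ADC units per mV.
#' @return `base`, invisibly.
#' @export
write_wfdb <- function(record, base, format = 212L, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  adc <- as.integer(round(record$samples * gain))
  n <- length(adc)
  name <- basename(base)
  hdr <- c(sprintf("%s 1 %.10g %d", name, record$fs, n),
           sprintf("%s.dat %d %g(0)/mV 12 0 %d 0 0 lead", name, format, gain, adc[1]))
  writeLines(hdr, paste0(base, ".hea"))

  if (format == 16L) {
    writeBin(adc, paste0(base, ".dat"), size = 2L, endian = "little")
  } else if (format == 212L) {
    if (any(adc > 2047L | adc < -2048L))
      stop("samples exceed 12-bit ADC range for format 212", call. = FALSE)
    v <- if (n %% 2L == 1L) c(adc, 0L) else adc
    v <- ifelse(v < 0L, v + 4096L, v)
    s1 <- v[seq(1L, length(v), 2L)]; s2 <- v[seq(2L, length(v), 2L)]
    tri <- rbind(bitwAnd(s1, 255L),
                 bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L)),
                 bitwAnd(s2, 255L))
    writeBin(as.raw(as.vector(tri)), paste0(base, ".dat"))
  } else stop("unsupported format: ", format, call. = FALSE)

  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    words <- integer()
    prev <- 0L
    for (j in seq_len(nrow(ann))) {
      cd <- unname(WFDB_BEAT_CODES[match(ann$type[j], names(WFDB_BEAT_CODES))])
      if (is.na(cd)) cd <- 1L  # unknown symbols written as normal beats
      diff <- (ann$sample[j] - 1L) - prev
      if (diff > 1023L) {
        words <- c(words, bitwShiftL(59L, 10L),
                   bitwShiftR(diff, 16L), bitwAnd(diff, 65535L))
        diff <- 0L
      }
      words <- c(words, bitwOr(bitwShiftL(cd, 10L), diff))
      prev <- ann$sample[j] - 1L
    }
    words <- c(words, 0L)
    con <- file(paste0(base, ".atr"), "wb")
    on.exit(close(con))
    writeBin(as.raw(as.vector(rbind(bitwAnd(words, 255L), bitwShiftR(words, 8L)))), con)
  }
  invisible(base)
}
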