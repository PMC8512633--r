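#!/usr/bin/env Rscript
# Optional: evaluate the detector on a local copy of the MIT-BIH arrhythmia
# database (not downloaded here; fetch it from PhysioNet yourself).
#
#   Rscript scripts/evaluate-mitdb.R --dir /path/to/mitdb [--records 100,101]
#       [--seed 1] [--out results/mitdb.json]
#
# Trains on the ROI dataset built from the first lead of the given records
# (80/20 stratified split by beat type) and reports window-level metrics plus
# end-to-end detection metrics and HRV per record. The published results
# additionally depend on unstated hyperparameters (QRS band edges, VMD
# penalty, SFS wrapper), so numbers here are indicative, not a reproduction.

suppressPackageStartupMessages({
  library(optparse)
  library(jsonlite)
  library(qrsdetect)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "mitdb"),
  make_option("--records", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/mitdb.json"))))

if (!dir.exists(opts$dir)) {
  message("MIT-BIH directory not found: ", opts$dir,
          " — nothing to do (this evaluation is optional).")
  quit(status = 0)
}

bases <- sub("\\.hea$", "", list.files(opts$dir, pattern = "\\.hea$",
                                       full.names = TRUE))
if (!is.null(opts$records)) {
  want <- strsplit(opts$records, ",")[[1]]
  bases <- bases[basename(bases) %in% want]
}
if (length(bases) == 0) stop("no WFDB records found under ", opts$dir)

message("reading ", length(bases), " records ...")
recs <- lapply(bases, read_wfdb)

model <- suppressWarnings(fit_rpeak_model(recs, seed = opts$seed))
print(model)

per_record <- list()
tp <- fp <- fn <- 0
locs <- list()
for (rec in recs) {
  det <- suppressWarnings(detect_rpeaks(rec, model, mode = "batch"))
  m <- match_detections(det, rec$annotations$sample, rec$fs)
  tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
  locs[[rec$name]] <- det
  per_record[[rec$name]] <- list(TP = m$TP, FP = m$FP, FN = m$FN)
}

overall <- classification_metrics(confusion_counts(tp, fp, 0, fn))
hrv_pooled <- aggregate_hrv(locs, recs[[1]]$fs, mode = "pooled")
hrv_mean <- aggregate_hrv(locs, recs[[1]]$fs, mode = "mean")

out <- list(
  n_records = length(recs),
  window_level = if (!is.null(model$test_metrics))
    model$test_metrics[c("sensitivity", "specificity", "precision",
                         "recall", "der", "accuracy")],
  detection = overall[c("sensitivity", "precision", "der", "accuracy")],
  hrv = list(pooled = hrv_pooled[c("mrr", "sdnn", "rmssd")],
             per_record_mean = hrv_mean[c("mrr", "sdnn", "rmssd")]),
  per_record = per_record)

dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
write_json(out, opts$out, auto_unbox = TRUE, digits = NA)
print(overall)
message("wrote ", opts$out)
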