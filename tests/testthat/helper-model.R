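# A small trained model shared across test files (lazily built once).
.test_cache <- new.env(parent = emptyenv())

get_test_model <- function() {
  if (is.null(.test_cache$model)) {
    recs <- synth_study(8, duration = 20, seed = 42)
    .test_cache$model <- suppressWarnings(fit_rpeak_model(recs, seed = 42))
  }
  .test_cache$model
}
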