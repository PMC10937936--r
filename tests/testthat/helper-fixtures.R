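# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code under fixed seeds; nothing is stored.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one clean synthesized /i/ vowel, preprocessed to 10 kHz
fixture_segment <- function(f0 = 150, formants = c(300, 2100, 2900),
                            duration = 0.8, noise_snr = 30, seed = 301) {
  .cached(paste0("seg_", f0, "_", paste(formants, collapse = "_")), function() {
    set.seed(seed)
    sp <- vowel_spec("i", f0, formants, duration = duration,
                     noise_snr = noise_snr)
    preprocess_segment(list(participant_id = "FIX", vowel = "i",
                            samples = synthesize_vowel(sp),
                            sample_rate = 15300))
  })
}

# a full default-sized cohort with extracted features (expensive; cached)
fixture_cohort_features <- function() {
  .cached("cohort_features", function() {
    co <- generate_cohort(cohort_params(seed = 424242))
    segs <- lapply(names(co$waveforms), function(k) {
      preprocess_segment(list(participant_id = sub("_[iuaeo]$", "", k),
                              vowel = sub("^.*_", "", k),
                              samples = co$waveforms[[k]],
                              sample_rate = 15300))
    })
    feats <- suppressWarnings(extract_features(segs))
    list(cohort = co, features = feats)
  })
}

# reduced-size estimator settings for tests that run the stack repeatedly;
# the properties under test (leakage, no-harm) do not depend on capacity
light_config <- list(rf_ntree = 120, mlp_epochs = 150, cnn_epochs = 100)

expect_within <- function(value, target, tol, label = NULL) {
  expect_true(abs(value - target) <= tol,
              info = paste0(label, ": |", signif(value, 6), " - ",
                            signif(target, 6), "| > ", signif(tol, 4)))
}
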