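sine_segment <- function(freq, dur = 1, fs = 10000, amp = 0.5) {
  structure(list(participant_id = "S", vowel = "i",
                 samples = amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs)),
                 sample_rate = fs),
            class = "vowel_segment")
}

test_that("pitch tracker is accurate on pure tones and synthesized vowels", {
  p <- estimate_pitch(sine_segment(200))
  expect_within(p[["pitch_mean"]], 200, 2, "sine pitch")

  seg <- fixture_segment(f0 = 150)
  p2 <- estimate_pitch(seg)
  expect_within(p2[["pitch_mean"]], 150, 3, "vowel pitch")

  set.seed(31)
  noise <- structure(list(samples = rnorm(10000), sample_rate = 10000),
                     class = "vowel_segment")
  expect_warning(pn <- estimate_pitch(noise), "unvoiced")
  expect_true(all(is.na(pn)))
})

test_that("LPC formants recover synthesized resonances within 7%", {
  seg <- fixture_segment(f0 = 150, formants = c(300, 2100, 2900))
  fm <- estimate_formants(seg)
  for (k in 1:3) {
    truth <- c(300, 2100, 2900)[k]
    expect_lt(abs(fm[[k]] - truth) / truth, 0.07)
  }
  expect_true(fm[["F1"]] < fm[["F2"]] && fm[["F2"]] < fm[["F3"]])

  # a pure sine has a single pole pair: missing sentinel
  expect_warning(fs <- estimate_formants(sine_segment(500)), "formants")
  expect_true(all(is.na(fs)))
})

test_that("Welch PSD satisfies Parseval and localizes tones", {
  set.seed(32)
  wn <- structure(list(samples = rnorm(20000), sample_rate = 10000),
                  class = "vowel_segment")
  p <- welch_psd(wn)
  expect_within(sum(p$density) * p$df, 1.0, 0.05, "integrated white-noise PSD")

  ps <- welch_psd(sine_segment(1000))
  expect_equal(ps$freq[which.max(ps$density)], 1000, tolerance = ps$df)

  # equal-amplitude band-interior tones split band power equally
  two <- structure(list(samples = 0.4 * sin(2 * pi * 300 * seq(0, 2, 1e-4)) +
                          0.4 * sin(2 * pi * 2200 * seq(0, 2, 1e-4)),
                        sample_rate = 10000),
                   class = "vowel_segment")
  bf <- band_features(welch_psd(two))
  p300 <- bf$relative_power[["b100_500"]]
  p2200 <- bf$relative_power[["b2000_2500"]]
  expect_lt(abs(p300 - p2200) / p300, 0.1)
})

test_that("band powers partition and centroids sit inside their bands", {
  seg <- fixture_segment()
  psd <- welch_psd(seg)
  bf <- band_features(psd)
  expect_equal(bf$relative_power[["b100_3000"]], 1.0)
  # six disjoint sub-bands partition the full band
  six <- bf$relative_power[c("b100_500", "b500_1000", "b1000_1500",
                             "b1500_2000", "b2000_2500", "b2500_3000")]
  expect_lt(abs(sum(six) - 1), 1e-6)
  b <- default_bands()
  for (i in seq_len(nrow(b))) {
    expect_gte(bf$spectral_centroid[[i]], b$low[i])
    expect_lte(bf$spectral_centroid[[i]], b$high[i])
  }
  # flat density -> centroid at the band middle
  flat <- structure(list(freq = psd$freq, density = rep(1, length(psd$freq)),
                         df = psd$df, fs = 10000), class = "welch_psd")
  bfl <- band_features(flat)
  expect_within(bfl$spectral_centroid[["b500_1000"]], 750, psd$df, "flat centroid")
})

test_that("MFCCs separate gain into coefficient zero only", {
  seg <- fixture_segment()
  m1 <- mfcc_features(seg)
  seg2 <- seg; seg2$samples <- seg$samples * 2
  m2 <- mfcc_features(seg2)
  expect_gt(abs(m2$mfcc_mean[[1]] - m1$mfcc_mean[[1]]), 0.1)
  expect_lt(max(abs(m2$mfcc_mean[-1] - m1$mfcc_mean[-1])), 1e-6)
  expect_lt(max(abs(m2$mfcc_sd - m1$mfcc_sd)), 1e-6)

  silence <- structure(list(samples = numeric(5000), sample_rate = 10000),
                       class = "vowel_segment")
  ms <- mfcc_features(silence)
  expect_true(all(ms$mfcc_sd == 0))
})

test_that("chroma, contrast, roll-off, ZCR and spectral shape behave as expected", {
  tone <- sine_segment(50 * 10000 / 512)  # on the analysis frequency grid
  mt <- misc_features(tone)
  # single tone: entropy far below the flat-spectrum maximum (~5 nats),
  # roll-off within one bin of the tone
  expect_lt(mt$spectral_entropy, 2.0)
  expect_within(mt$rolloff_mean, 50 * 10000 / 512, 10000 / 512 + 1,
                "tone roll-off")
  expect_true(all(mt$chroma_mean >= 0 & mt$chroma_mean <= 1))

  # flat PSD over the analysis band: zero skewness, entropy = ln(#bins)
  seg <- fixture_segment()
  psd <- welch_psd(seg)
  flat <- structure(list(freq = psd$freq, density = rep(1, length(psd$freq)),
                         df = psd$df, fs = 10000), class = "welch_psd")
  mf <- misc_features(seg, psd = flat)
  nbins <- sum(psd$freq >= 100 & psd$freq < 3000)
  expect_within(mf$spectral_skewness, 0, 0.05, "flat skewness")
  expect_within(mf$spectral_entropy, log(nbins), 0.01 * log(nbins), "flat entropy")

  # square wave at 250 Hz: 2 * 250 / 10000 crossings per sample
  sq <- structure(list(samples = sign(sin(2 * pi * 250 * seq(0, 1, 1e-4))),
                       sample_rate = 10000),
                  class = "vowel_segment")
  ms <- misc_features(sq)
  expect_within(ms$zcr_mean, 0.05, 0.005, "square-wave ZCR")
})

test_that("the full feature vector has 106 scalars, fixed order, deterministic", {
  seg <- fixture_segment()
  v <- extract_all(seg)
  expect_length(v, 106)
  expect_identical(names(v), feature_names())
  v2 <- extract_all(seg)
  expect_identical(v, v2)
  expect_true(v[["F1"]] < v[["F2"]] && v[["F2"]] < v[["F3"]])
  expect_true(all(v[grep("^relative_power", names(v))] >= 0))
  expect_true(all(v[grep("^relative_power", names(v))] <= 1 + 1e-12))

  short <- structure(list(samples = rnorm(1000), sample_rate = 10000),
                     class = "vowel_segment")
  expect_error(extract_all(short), "too short")
})

test_that("amplitude scaling leaves scale-free features invariant", {
  seg <- fixture_segment()
  v1 <- extract_all(seg)
  seg2 <- seg; seg2$samples <- seg$samples * 3
  v2 <- extract_all(seg2)
  scale_free <- c("pitch_mean", "pitch_sd", "F1", "F2", "F3",
                  grep("^relative_power|^spectral_centroid|^chroma|^zcr",
                       names(v1), value = TRUE),
                  "spectral_skewness", "spectral_kurtosis", "spectral_entropy")
  for (nm in scale_free) {
    denom <- max(abs(v1[[nm]]), 1)
    expect_lt(abs(v2[[nm]] - v1[[nm]]) / denom, 1e-6)
  }
  # absolute band powers shift by 20*log10(3) dB
  bp <- grep("^band_power", names(v1), value = TRUE)
  expect_equal(unname(v2[bp] - v1[bp]), rep(20 * log10(3), 10),
               tolerance = 1e-6)
})

test_that("MFCCs agree with an independent reference implementation within 1%", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  seg <- fixture_segment()
  fin <- withr::local_tempfile(fileext = ".csv")
  fout <- withr::local_tempfile(fileext = ".csv")
  write(format(seg$samples, digits = 17), fin, ncolumns = 1)
  status <- system2(py, c(test_path("mfcc_oracle.py"), fin,
                          seg$sample_rate, fout))
  expect_equal(status, 0L)
  ref <- read.csv(fout)
  ours <- mfcc_features(seg)
  tol_mean <- 0.01 * max(abs(ref$mean))
  tol_sd <- 0.01 * max(abs(ref$sd))
  expect_lt(max(abs(unname(ours$mfcc_mean) - ref$mean)), tol_mean)
  expect_lt(max(abs(unname(ours$mfcc_sd) - ref$sd)), tol_sd)
})
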