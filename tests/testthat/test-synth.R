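test_that("generated participants always satisfy the NoSAS group constraint", {
  set.seed(10)
  for (g in c("control", "osa")) {
    for (i in 1:40) {
      p <- generate_participant(g, id = sprintf("%s%02d", g, i))
      sc <- nosas_score(p$neck_circumference, p$bmi, p$snoring, p$age, p$sex)
      if (g == "control") expect_lt(sc$score, 8) else expect_gte(sc$score, 8)
      expect_gte(p$age, 18)
    }
  }
})

test_that("control demographics recover the configured means", {
  # rejection sampling against NoSAS slightly reshapes the marginals, so
  # the band is wider than the pure-sampling standard error
  set.seed(11)
  prof <- replicate(2000, {
    p <- generate_participant("control")
    c(p$age, p$bmi)
  })
  expect_within(mean(prof[1, ]), 35.11, 1.0, "control mean age")
  expect_within(mean(prof[2, ]), 24.73, 0.5, "control mean BMI")
})

test_that("PAP sampling averages five replicates and respects degenerate SD", {
  set.seed(12)
  m <- sample_pap("control", "i", participant_id = "P1")
  expect_equal(m$pap_mm, mean(m$replicate_values))
  expect_length(m$replicate_values, 5)
  expect_gt(m$pap_mm, 0)

  pz <- cohort_params()
  pz$pap_sd[] <- 0
  pz$replicate_sd <- 0
  z <- sample_pap("osa", "a", pz)
  expect_equal(z$pap_mm, pz$pap_mean["osa", "a"])

  expect_error(sample_pap("control", "x"), "no PAP parameters")
})

test_that("PAP sampler recovers a configured cell mean", {
  set.seed(13)
  draws <- replicate(4000, sample_pap("control", "i")$pap_mm)
  se <- sd(draws) / sqrt(length(draws))
  expect_within(mean(draws), 26.9, 3 * se, "control /i/ PAP mean")
})

test_that("synthesized vowels are periodic at f0 and resonant at the formants", {
  sp <- vowel_spec("i", 200, c(300, 2100, 2900), duration = 0.5,
                   noise_snr = Inf, jitter = 0)
  set.seed(14)
  x <- synthesize_vowel(sp)
  expect_equal(max(abs(x)), 0.5)
  expect_equal(length(x), round(0.5 * 15300))
  # autocorrelation-based period within one sample of 1/200 s
  ac <- acf(x, lag.max = 120, plot = FALSE)$acf[-1]
  lag_range <- 40:110                      # exclude the zero-lag shoulder
  per <- lag_range[which.max(ac[lag_range])]
  expect_lte(abs(per - 15300 / 200), 1)

  # spectral-envelope peaks near each formant: low f0 so harmonics sample
  # the envelope densely, Welch smoothing to merge harmonics, pre-emphasis
  # to flatten the glottal source tilt that otherwise buries F1
  sp2 <- vowel_spec("i", 90, c(300, 2100, 2900), duration = 0.8,
                    noise_snr = 40)
  set.seed(15)
  y <- synthesize_vowel(sp2)
  yp <- y[-1] - 0.97 * y[-length(y)]
  p <- welch_psd(list(samples = yp, sample_rate = 15300))
  for (fm in sp2$formants) {
    near <- p$freq > fm - 200 & p$freq < fm + 200
    peak_f <- p$freq[near][which.max(p$density[near])]
    expect_within(peak_f, fm, 50, paste("formant peak", fm))
  }
})

test_that("synthesis is bit-identical under a fixed seed and errors above Nyquist", {
  sp <- vowel_spec("a", 150, c(700, 1200, 2500), duration = 0.4)
  set.seed(16); x1 <- synthesize_vowel(sp)
  set.seed(16); x2 <- synthesize_vowel(sp)
  expect_identical(x1, x2)
  expect_error(vowel_spec("a", 150, c(700, 1200, 8000)), "Nyquist")
  expect_error(vowel_spec("a", 150, c(1200, 700, 2500)), "F1 < F2 < F3")
  expect_error(vowel_spec("a", 30, c(700, 1200, 2500)), "60-400")
  expect_error(vowel_spec("a", 150, c(700, 1200, 2500), duration = 0.1),
               "duration")
})

test_that("cohorts have the right shape and are reproducible from the seed", {
  params <- cohort_params(seed = 77)
  c1 <- generate_cohort(params, audio = FALSE)
  expect_equal(nrow(c1$profiles), 31)
  expect_equal(nrow(c1$pap), 155)
  expect_equal(nrow(c1$specs), 155)
  c2 <- generate_cohort(params, audio = FALSE)
  expect_identical(c1$specs, c2$specs)
  expect_identical(c1$pap, c2$pap)
  c3 <- generate_cohort(cohort_params(seed = 78), audio = FALSE)
  expect_false(identical(c1$specs$f0, c3$specs$f0))

  tiny <- generate_cohort(cohort_params(n_control = 1, n_osa = 0, seed = 5))
  expect_length(tiny$waveforms, 5)
  expect_equal(nrow(tiny$pap), 5)
  set.seed(99)
  w1 <- generate_cohort(cohort_params(n_control = 1, n_osa = 0, seed = 5))
  expect_identical(tiny$waveforms, w1$waveforms)
})

test_that("zero coupling decouples true F2 from PAP", {
  sp <- generate_cohort(cohort_params(coupling = 0, seed = 303),
                        audio = FALSE)
  m <- merge(sp$specs, sp$pap, by = c("participant_id", "vowel"))
  # within-vowel correlation (pooling vowels would confound vowel identity)
  rs <- vapply(unique(m$vowel), function(v) {
    s <- m[m$vowel == v, ]
    cor(s$F2, s$pap_mm)
  }, numeric(1))
  # n = 31 per vowel: null 2.5 SE band
  expect_true(all(abs(rs) < 2.5 / sqrt(31)))
})

test_that("written cohorts read back through the annotation chain", {
  co <- generate_cohort(cohort_params(n_control = 1, n_osa = 1, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_length(list.files(dir, pattern = "\\.wav$"), 10)
  expect_true(file.exists(file.path(dir, "demographics.csv")))
  w <- list.files(dir, pattern = "_i\\.wav$", full.names = TRUE)[1]
  tg <- sub("\\.wav$", ".TextGrid", w)
  segs <- read_segments(w, tg)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$vowel, "i")
  key <- sub("\\.wav$", "", basename(w))
  # sliced samples match the synthesized waveform up to 16-bit quantization
  expect_lt(max(abs(segs[[1]]$samples - co$waveforms[[key]])), 2 / 32767)
})
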