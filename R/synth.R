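#' Cohort generation parameters
#'
#' Bundles every distributional parameter of the synthetic cohort: group
#' sizes, per-(group, vowel) Gaussians for the parasagittal anterior-posterior
#' (PAP) airway diameter, fundamental frequency and second formant, per-vowel
#' F1/F3 tables, demographic Gaussians per group, and the latent-coupling
#' structure that ties a participant's airway openness to their acoustics.
#'
#' Defaults reproduce the study conditions: 18 controls vs 13 high-risk-OSA
#' participants; PAP (mm) for (control, /i/) 26.9 +/- 6.0, (osa, /i/)
#' 19.1 +/- 7.9, (control, /a/) 4.3 +/- 2.0, (osa, /a/) 6.3 +/- 2.5; pitch
#' (Hz) (control, /i/) 199.7 +/- 43.0, (osa, /i/) 166.8 +/- 39.2,
#' (control, /a/) 194.7 +/- 37.3, (osa, /a/) 159.2 +/- 36.2; F2 (Hz)
#' (control, /i/) 2021.7 +/- 420.7, (osa, /i/) 1690.2 +/- 204.2,
#' (control, /a/) 1243.1 +/- 160.1, (osa, /a/) 1219.1 +/- 101.5.
#' The vowels /u/, /e/, /o/ have no published group statistics; their
#' defaults interpolate between the /i/ and /a/ cells so that frontal vowels
#' (/i/, /u/) have wide airways and back vowels (/a/, /e/, /o/) narrow ones,
#' and their formant targets follow standard adult vowel tables.
#'
#' @param n_control,n_osa Group sizes.
#' @param coupling Loading of the participant's latent airway openness on
#'   the acoustic parameters (F2 and glottal spectral balance), in \[0, 1\].
#'   0 decouples acoustics from PAP.
#' @param pap_loading Within-participant loading of the openness latent on
#'   PAP across vowels (controls the See-Sah delta variance).
#' @param f0_loading Within-participant loading of the voice latent on pitch.
#' @param seed Integer seed from which all cohort randomness derives.
#' @param ... Named overrides for any other element of the default list
#'   (e.g. `pap_mean`, `f2_sd`, `duration_range`, `noise_snr`); unknown
#'   names are an error.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_control = 18, n_osa = 13, coupling = 0.7,
                          pap_loading = 0.9, f0_loading = 0.95,
                          seed = 1L, ...) {
  groups <- c("control", "osa")
  vowels <- c("i", "u", "a", "e", "o")
  m <- function(ctrl, osa) matrix(c(ctrl, osa), nrow = 2, byrow = TRUE,
                                  dimnames = list(groups, vowels))
  p <- list(
    n_control = n_control, n_osa = n_osa, seed = as.integer(seed),
    vowels = vowels,
    vowel_words = c(i = "see", u = "soo", a = "sah", e = "set", o = "so"),
    # PAP diameter (mm): /i/ and /a/ cells from the study; /u/,/e/,/o/
    # interpolated with frontal > back ordering and OSA>control on back vowels
    pap_mean = m(c(26.9, 24.0, 4.3, 6.5, 5.5), c(19.1, 17.5, 6.3, 7.5, 7.0)),
    pap_sd   = m(c(6.0, 5.5, 2.0, 2.5, 2.2),   c(7.9, 7.0, 2.5, 3.0, 2.8)),
    # fundamental frequency (Hz)
    f0_mean = m(c(199.7, 197.0, 194.7, 196.0, 196.5),
                c(166.8, 164.0, 159.2, 161.0, 162.0)),
    f0_sd   = m(c(43.0, 40.0, 37.3, 39.0, 39.0),
                c(39.2, 37.0, 36.2, 37.0, 37.0)),
    # second formant (Hz)
    f2_mean = m(c(2021.7, 950, 1243.1, 1770, 1000),
                c(1690.2, 900, 1219.1, 1600, 950)),
    f2_sd   = m(c(420.7, 120, 160.1, 200, 130),
                c(204.2, 110, 101.5, 180, 120)),
    # F1/F3 per vowel (standard adult tables; not group-specific)
    f1_mean = c(i = 300, u = 350, a = 730, e = 550, o = 500),
    f1_sd   = c(i = 30,  u = 35,  a = 70,  e = 55,  o = 50),
    f3_mean = c(i = 2900, u = 2350, a = 2550, e = 2650, o = 2450),
    f3_sd   = c(i = 90,   u = 90,   a = 90,   e = 90,   o = 90),
    formant_bandwidths = c(80, 120, 160),
    # demographics per group (Table-style Gaussians + Bernoulli sex/snoring)
    demo = list(
      control = list(age = c(35.11, 11.97), bmi = c(24.73, 3.74),
                     nc = c(33.59, 5.64), p_male = 5 / 18, p_snore = 0.20),
      osa     = list(age = c(54.54, 11.59), bmi = c(33.29, 5.77),
                     nc = c(34.21, 3.30), p_male = 7 / 13, p_snore = 0.85)
    ),
    coupling = coupling, pap_loading = pap_loading, f0_loading = f0_loading,
    replicate_sd = 0.3,            # mm, sonographer re-measurement noise
    duration_range = c(0.6, 1.0),  # s, sustained utterance length
    noise_snr = 30,                # dB, aspiration/recording noise
    jitter = 0.005,                # relative period perturbation
    sample_rate = 15300
  )
  extra <- list(...)
  bad <- setdiff(names(extra), names(p))
  if (length(bad)) stop("unknown cohort_params fields: ", paste(bad, collapse = ", "))
  p[names(extra)] <- extra
  structure(p, class = "cohort_params")
}

# deterministic child seed per pipeline stage, kept below 2^31
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h * 16807) %% 2147483647
}

# pre-truncation mean such that a normal truncated below at `lower`
# has mean `target`
.trunc_norm_mu <- function(target, sd, lower) {
  if (lower < target - 6 * sd) return(target)
  f <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a)) - target
  }
  uniroot(f, c(target - 6 * sd, target + sd))$root
}

.rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop("truncated-normal rejection sampling failed for mean=", mean, " sd=", sd)
}

# exact inverse-CDF draw from N(base, s) truncated to (lower, upper);
# used for the vowel-level noise conditional on a participant latent,
# where rejection sampling can become infeasible for extreme latents
.rcondtrunc1 <- function(base, s, lower = -Inf, upper = Inf) {
  if (s <= 0) {
    if (base > lower && base < upper) return(base)
    stop("degenerate conditional truncation: base ", signif(base, 4),
         " outside (", lower, ", ", upper, ")")
  }
  p_lo <- pnorm((lower - base) / s)
  p_hi <- pnorm((upper - base) / s)
  if (p_hi - p_lo < 1e-12)
    stop("conditional truncation infeasible: N(", signif(base, 4), ", ",
         signif(s, 4), ") on (", lower, ", ", upper, ")")
  base + s * qnorm(runif(1, p_lo, p_hi))
}

#' Generate one participant profile
#'
#' Samples demographics from the group-specific Gaussians/Bernoullis and
#' rejection-samples until the NoSAS label is consistent with the requested
#' group (controls must score < 8, the OSA group >= 8). Age is drawn from a
#' truncated-at-18 Gaussian whose pre-truncation mean is corrected so the
#' generated population mean equals the configured mean.
#'
#' Uses the current R random-number state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param group `"control"` or `"osa"`.
#' @param params A [cohort_params()] list.
#' @param id Participant identifier string.
#' @param max_tries Rejection-sampling attempt bound.
#' @return A list of class `participant_profile` with fields
#'   `participant_id`, `group`, `sex`, `age`, `bmi`, `neck_circumference`,
#'   `snoring`.
#' @export
generate_participant <- function(group = c("control", "osa"),
                                 params = cohort_params(),
                                 id = "P001", max_tries = 1000) {
  group <- match.arg(group)
  d <- params$demo[[group]]
  age_mu <- .trunc_norm_mu(d$age[1], d$age[2], 18)
  for (i in seq_len(max_tries)) {
    prof <- list(
      participant_id = id,
      group = group,
      sex = if (runif(1) < d$p_male) "M" else "F",
      age = as.integer(round(.rtruncnorm1(age_mu, d$age[2], lower = 17.5))),
      bmi = .rtruncnorm1(d$bmi[1], d$bmi[2], lower = 14),
      neck_circumference = .rtruncnorm1(d$nc[1], d$nc[2], lower = 25),
      snoring = runif(1) < d$p_snore
    )
    sc <- nosas_score(prof$neck_circumference, prof$bmi, prof$snoring,
                      prof$age, prof$sex)
    ok <- if (group == "control") !sc$high_risk else sc$high_risk
    if (ok) return(structure(prof, class = "participant_profile"))
  }
  stop("generate_participant: could not satisfy the NoSAS constraint for group '",
       group, "' in ", max_tries, " attempts; parameterization infeasible")
}

#' Sample one PAP diameter measurement
#'
#' Draws the participant's true diameter from the (group, vowel) Gaussian
#' (truncated at zero by resampling, which preserves the mean when the mass
#' below zero is small), then simulates the sonographer's five replicate
#' caliper readings around it and averages them.
#'
#' @param group,vowel Cell selectors.
#' @param params A [cohort_params()] list.
#' @param z Optional latent airway-openness value shared across this
#'   participant's vowels; drawn N(0,1) if missing.
#' @param participant_id Identifier recorded in the result.
#' @return A list of class `pap_measurement` with `participant_id`, `vowel`,
#'   `pap_mm` (the mean of the replicates) and `replicate_values` (5 values,
#'   mm).
#' @export
sample_pap <- function(group, vowel, params = cohort_params(), z = NULL,
                       participant_id = NA_character_) {
  if (!group %in% rownames(params$pap_mean) || !vowel %in% colnames(params$pap_mean))
    stop("sample_pap: no PAP parameters configured for (", group, ", ", vowel, ")")
  mu <- params$pap_mean[group, vowel]
  sd <- params$pap_sd[group, vowel]
  lam <- params$pap_loading
  if (is.null(z)) z <- rnorm(1)
  base <- mu + sd * sqrt(lam) * z
  noise_sd <- sd * sqrt(1 - lam)
  if (noise_sd > 0) {
    # sample the vowel-specific noise from its exact conditional
    # truncated normal (value must stay positive even for extreme z)
    p_lo <- pnorm(-base / noise_sd)
    if (p_lo >= 1 - 1e-12)
      stop("sample_pap: zero-truncation infeasible for (", group, ", ",
           vowel, ") at z = ", signif(z, 3))
    value <- base + noise_sd * qnorm(runif(1, p_lo, 1))
  } else {
    value <- base
    if (value <= 0)
      stop("sample_pap: non-positive degenerate PAP for (", group, ", ", vowel, ")")
  }
  repeat {
    reps <- value + rnorm(5, 0, params$replicate_sd)
    if (all(reps > 0)) break
  }
  structure(list(participant_id = participant_id, vowel = vowel,
                 pap_mm = mean(reps), replicate_values = reps),
            class = "pap_measurement")
}

#' Specification of one synthetic vowel utterance
#'
#' @param vowel One of `"i" "u" "a" "e" "o"`.
#' @param f0 Fundamental frequency, Hz (60-400).
#' @param formants Numeric triple (F1, F2, F3), Hz, strictly increasing.
#' @param formant_bandwidths Resonator -3 dB bandwidths, Hz.
#' @param duration Utterance length, s (> 0.2).
#' @param noise_snr Additive-noise SNR, dB.
#' @param sample_rate Output sampling rate, Hz.
#' @param oq Glottal open quotient (spectral-balance control), in \[0.35, 0.85\].
#' @param jitter Relative pitch-period perturbation (<= 0.01).
#' @return A list of class `vowel_spec`.
#' @export
vowel_spec <- function(vowel, f0, formants,
                       formant_bandwidths = c(80, 120, 160),
                       duration = 0.8, noise_snr = 30,
                       sample_rate = 15300, oq = 0.6, jitter = 0.005) {
  stopifnot(length(formants) == 3)
  if (!(formants[1] > 0 && formants[1] < formants[2] && formants[2] < formants[3]))
    stop("vowel_spec: formants must satisfy 0 < F1 < F2 < F3")
  if (f0 < 60 || f0 > 400) stop("vowel_spec: f0 must lie in 60-400 Hz")
  if (duration <= 0.2) stop("vowel_spec: duration must exceed 0.2 s")
  if (max(formants) >= sample_rate / 2)
    stop("vowel_spec: formant at or above Nyquist (", sample_rate / 2, " Hz)")
  structure(list(vowel = vowel, f0 = f0, formants = as.numeric(formants),
                 formant_bandwidths = as.numeric(formant_bandwidths),
                 duration = duration, noise_snr = noise_snr,
                 sample_rate = sample_rate, oq = oq, jitter = jitter),
            class = "vowel_spec")
}

# Rosenberg glottal flow pulse sampled at n points over one open phase
.rosenberg_pulse <- function(n_open, n_total) {
  np <- max(2L, round(n_open * 2 / 3))       # opening phase
  nn <- max(1L, n_open - np)                 # closing phase
  t1 <- seq_len(np) / np
  t2 <- seq_len(nn) / nn
  pulse <- c(0.5 * (1 - cos(pi * t1)), cos(pi * t2 / 2))
  c(pulse, rep(0, max(0, n_total - length(pulse))))[seq_len(n_total)]
}

#' Synthesize a vowel waveform from a source-filter specification
#'
#' A Rosenberg-type glottal pulse train at `f0` (with small period jitter)
#' is differentiated (lip-radiation approximation) and passed through a
#' cascade of three impulse-invariant second-order resonators at the
#' specified formants; Gaussian noise is added at `noise_snr` and the peak
#' amplitude is normalized to 0.5 full scale.
#'
#' Deterministic under a fixed R random-number state.
#'
#' @param spec A [vowel_spec()].
#' @return Numeric waveform vector of `round(duration * sample_rate)`
#'   samples, peak 0.5.
#' @export
synthesize_vowel <- function(spec) {
  stopifnot(inherits(spec, "vowel_spec"))
  fs <- spec$sample_rate
  n_out <- round(spec$duration * fs)
  # glottal pulse train with jittered periods
  src <- numeric(n_out + ceiling(fs / spec$f0) + 1)
  pos <- 1L
  while (pos <= n_out) {
    period <- fs / spec$f0
    if (spec$jitter > 0) period <- period * (1 + rnorm(1, 0, spec$jitter))
    nT <- max(4L, round(period))
    n_open <- max(3L, round(spec$oq * nT))
    src[pos:(pos + nT - 1L)] <- src[pos:(pos + nT - 1L)] + .rosenberg_pulse(n_open, nT)
    pos <- pos + nT
  }
  x <- diff(src)[seq_len(n_out)]  # radiation: first difference
  # cascade of three second-order resonators (impulse invariant)
  for (k in 1:3) {
    r <- exp(-pi * spec$formant_bandwidths[k] / fs)
    th <- 2 * pi * spec$formants[k] / fs
    x <- stats::filter(x, filter = c(2 * r * cos(th), -r^2), method = "recursive")
  }
  x <- as.numeric(x)
  if (is.finite(spec$noise_snr)) {
    sig_p <- mean(x^2)
    x <- x + rnorm(n_out, 0, sqrt(sig_p / 10^(spec$noise_snr / 10)))
  }
  x / max(abs(x)) * 0.5
}

#' Generate a full synthetic cohort
#'
#' Produces demographics (NoSAS-consistent), per-vowel PAP measurements and
#' per-vowel waveform specifications/waveforms for `n_control + n_osa`
#' participants. Each participant carries a latent airway-openness value `z`
#' and a latent voice value `w`; `z` loads on PAP (loading `pap_loading`)
#' and, through `coupling`, on F2 and the glottal open quotient, so
#' feature-PAP correlation is recoverable downstream; `w` loads on pitch.
#' Fully reproducible from `params$seed`.
#'
#' @param params A [cohort_params()] list.
#' @param audio If `FALSE`, skip waveform synthesis (specs are still
#'   generated); used when only tabular outputs are needed.
#' @return A list of class `vowel_cohort` with data.frames `profiles`,
#'   `pap`, `specs` (the ground-truth sidecar incl. latents) and a named
#'   list `waveforms` (`"<pid>_<vowel>"`, empty if `audio = FALSE`).
#' @export
generate_cohort <- function(params = cohort_params(), audio = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(params$seed, "cohort"))

  groups <- c(rep("control", params$n_control), rep("osa", params$n_osa))
  ids <- sprintf("P%03d", seq_along(groups))
  profiles <- NULL; pap <- NULL; specs <- NULL
  waveforms <- list()

  for (j in seq_along(ids)) {
    g <- groups[j]
    prof <- generate_participant(g, params, id = ids[j])
    profiles <- rbind(profiles, as.data.frame(unclass(prof), stringsAsFactors = FALSE))
    # participant latents, truncated to +/-3 so that vowel-level draws
    # conditional on them keep usable mass inside physiological ranges
    z <- .rcondtrunc1(0, 1, -3, 3)  # airway openness
    w <- .rcondtrunc1(0, 1, -3, 3)  # voice
    for (v in params$vowels) {
      pm <- sample_pap(g, v, params, z = z, participant_id = ids[j])
      pap <- rbind(pap, data.frame(
        participant_id = ids[j], group = g, vowel = v, pap_mm = pm$pap_mm,
        t(setNames(pm$replicate_values, paste0("rep", 1:5)))))
      lf <- params$f0_loading
      f0 <- .rcondtrunc1(params$f0_mean[g, v] + params$f0_sd[g, v] * sqrt(lf) * w,
                         params$f0_sd[g, v] * sqrt(1 - lf), 80, 380)
      cc <- params$coupling
      f1 <- .rtruncnorm1(params$f1_mean[v], params$f1_sd[v], lower = 150)
      f3 <- params$f3_mean[v] + params$f3_sd[v] * rnorm(1)
      f2 <- .rcondtrunc1(params$f2_mean[g, v] + params$f2_sd[g, v] * cc * z,
                         params$f2_sd[g, v] * sqrt(1 - cc^2),
                         f1 + 120, f3 - 120)
      oq <- min(0.8, max(0.4, 0.6 + 0.04 * cc * z))
      dur <- runif(1, params$duration_range[1], params$duration_range[2])
      sp <- vowel_spec(v, f0, c(f1, f2, f3), params$formant_bandwidths,
                       duration = dur, noise_snr = params$noise_snr,
                       sample_rate = params$sample_rate, oq = oq,
                       jitter = params$jitter)
      specs <- rbind(specs, data.frame(
        participant_id = ids[j], group = g, vowel = v, f0 = f0,
        F1 = f1, F2 = f2, F3 = f3, duration = dur, oq = oq, z = z, w = w))
      if (audio) waveforms[[paste0(ids[j], "_", v)]] <- synthesize_vowel(sp)
    }
  }
  structure(list(profiles = profiles, pap = pap, specs = specs,
                 waveforms = waveforms, params = params),
            class = "vowel_cohort")
}

#' @export
print.vowel_cohort <- function(x, ...) {
  cat("Synthetic vowel cohort:", nrow(x$profiles), "participants (",
      sum(x$profiles$group == "control"), "control /",
      sum(x$profiles$group == "osa"), "OSA ),",
      nrow(x$pap), "PAP measurements,",
      length(x$waveforms), "waveforms\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one 16-bit PCM WAV and one PRAAT TextGrid per participant x vowel
#' (`<pid>_<vowel>.wav/.TextGrid`; the vowel interval is framed by 0.1 s of
#' silence so the annotation reader is exercised), plus `demographics.csv`,
#' `pap.csv` and the ground-truth sidecar `specs.csv`.
#'
#' @param cohort A [generate_cohort()] result with waveforms.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vowel_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- cohort$params$sample_rate
  pad <- round(0.1 * fs)
  for (key in names(cohort$waveforms)) {
    x <- cohort$waveforms[[key]]
    y <- c(numeric(pad), x, numeric(pad))
    write_wav(y, fs, file.path(dir, paste0(key, ".wav")))
    v <- sub("^.*_", "", key)
    write_textgrid(
      data.frame(xmin = pad / fs, xmax = (pad + length(x)) / fs, label = v),
      file.path(dir, paste0(key, ".TextGrid")),
      xmax = length(y) / fs)
  }
  utils::write.csv(cohort$profiles, file.path(dir, "demographics.csv"), row.names = FALSE)
  utils::write.csv(cohort$pap, file.path(dir, "pap.csv"), row.names = FALSE)
  utils::write.csv(cohort$specs, file.path(dir, "specs.csv"), row.names = FALSE)
  invisible(dir)
}
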