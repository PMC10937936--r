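# Acoustic feature extraction for 10 kHz band-passed vowel segments.
# All frame-based analyses use 20 ms windows unless noted; the pitch
# tracker uses 40 ms so that two periods of a 60 Hz voice fit in a frame.

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# short-time one-sided power spectrogram: returns bins x frames matrix
.stft_power <- function(x, fs, win = 200, hop = 100, nfft = 512) {
  starts <- seq(1, length(x) - win + 1, by = hop)
  w <- .hamming(win)
  fr <- vapply(starts, function(s) x[s:(s + win - 1)] * w, numeric(win))
  fr <- rbind(fr, matrix(0, nfft - win, length(starts)))
  X <- stats::mvfft(fr)
  nb <- nfft / 2 + 1
  list(P = abs(X[1:nb, , drop = FALSE])^2,
       freq = (0:(nb - 1)) * fs / nfft,
       n_frames = length(starts))
}

.seg_check <- function(seg, min_duration = 0.2) {
  stopifnot(!is.null(seg$samples), !is.null(seg$sample_rate))
  if (length(seg$samples) / seg$sample_rate < min_duration)
    stop("segment too short (",
         sprintf("%.3f", length(seg$samples) / seg$sample_rate),
         " s < ", min_duration, " s)")
  invisible(seg)
}

#' Pitch estimation by normalized cross-correlation tracking
#'
#' RAPT-style tracker: per 40 ms frame, the normalized cross-correlation
#' function (NCCF) over lags corresponding to 60-400 Hz yields pitch
#' candidates (local maxima, parabolic lag interpolation); a dynamic
#' program selects the smoothest candidate path, with a transition cost on
#' octave jumps and a small preference for shorter lags to resist period
#' doubling. Frames whose best NCCF falls below `voicing_threshold` are
#' unvoiced and excluded from the summary.
#'
#' @param seg A `vowel_segment` (10 kHz).
#' @param fmin,fmax Search range, Hz.
#' @param voicing_threshold Minimum NCCF for a voiced frame (default 0.3).
#' @param frame_s,hop_s Analysis frame length and hop, seconds.
#' @return Named numeric `c(pitch_mean, pitch_sd)` in Hz; both `NA` (with a
#'   warning) if every frame is unvoiced.
#' @export
estimate_pitch <- function(seg, fmin = 60, fmax = 400,
                           voicing_threshold = 0.3,
                           frame_s = 0.04, hop_s = 0.01) {
  .seg_check(seg)
  x <- seg$samples - mean(seg$samples)
  fs <- seg$sample_rate
  n <- round(frame_s * fs)
  lmin <- max(2L, floor(fs / fmax))
  lmax <- ceiling(fs / fmin)
  len <- length(x)
  starts <- seq(1, len - n - lmax, by = round(hop_s * fs))
  if (length(starts) == 0) {
    warning("estimate_pitch: segment too short for the lag range")
    return(c(pitch_mean = NA_real_, pitch_sd = NA_real_))
  }
  lags <- lmin:lmax
  csq <- cumsum(c(0, x^2))
  e0 <- csq[starts + n] - csq[starts]
  nccf <- matrix(0, length(starts), length(lags))
  for (j in seq_along(lags)) {
    l <- lags[j]
    cp <- cumsum(c(0, x[1:(len - l)] * x[(1 + l):len]))
    cross <- cp[starts + n] - cp[starts]
    el <- csq[starts + l + n] - csq[starts + l]
    nccf[, j] <- cross / sqrt(pmax(e0 * el, 1e-30))
  }
  # per-frame candidates: local NCCF maxima above threshold, top 5
  n_cand <- 5L
  cand_lag <- matrix(NA_real_, length(starts), n_cand)
  cand_val <- matrix(-Inf, length(starts), n_cand)
  for (i in seq_along(starts)) {
    v <- nccf[i, ]
    pk <- which(diff(sign(diff(v))) == -2) + 1
    pk <- pk[v[pk] >= voicing_threshold]
    if (length(pk) == 0) next
    pk <- pk[order(v[pk], decreasing = TRUE)][seq_len(min(n_cand, length(pk)))]
    for (k in seq_along(pk)) {
      j <- pk[k]
      # parabolic interpolation of the lag
      num <- v[j - 1] - v[j + 1]
      den <- v[j - 1] - 2 * v[j] + v[j + 1]
      d <- if (abs(den) > 1e-12) 0.5 * num / den else 0
      cand_lag[i, k] <- lags[j] + max(-0.5, min(0.5, d))
      cand_val[i, k] <- v[j]
    }
  }
  voiced <- which(is.finite(cand_val[, 1]))
  if (length(voiced) == 0) {
    warning("estimate_pitch: fully unvoiced segment")
    return(c(pitch_mean = NA_real_, pitch_sd = NA_real_))
  }
  # dynamic programming over contiguous voiced runs
  f0 <- rep(NA_real_, length(starts))
  runs <- split(voiced, cumsum(c(1, diff(voiced) != 1)))
  for (run in runs) {
    nc <- rowSums(is.finite(cand_val[run, , drop = FALSE]))
    cost <- matrix(Inf, length(run), n_cand)
    back <- matrix(0L, length(run), n_cand)
    local <- (1 - cand_val[run, , drop = FALSE]) +
      0.05 * log2(cand_lag[run, , drop = FALSE] / lmin)
    cost[1, seq_len(nc[1])] <- local[1, seq_len(nc[1])]
    if (length(run) > 1) for (t in 2:length(run)) {
      for (j in seq_len(nc[t])) {
        tr <- cost[t - 1, seq_len(nc[t - 1])] +
          0.4 * abs(log2(cand_lag[run[t], j] / cand_lag[run[t - 1], seq_len(nc[t - 1])]))
        b <- which.min(tr)
        cost[t, j] <- tr[b] + local[t, j]
        back[t, j] <- b
      }
    }
    j <- which.min(cost[length(run), ])
    for (t in rev(seq_along(run))) {
      f0[run[t]] <- fs / cand_lag[run[t], j]
      if (t > 1) j <- back[t, j]
    }
  }
  f0 <- f0[is.finite(f0)]
  c(pitch_mean = mean(f0), pitch_sd = if (length(f0) > 1) sd(f0) else 0)
}

#' Formant estimation from the 8th-order LPC spectrum
#'
#' Per 20 ms Hamming frame of the pre-emphasized segment, autocorrelation
#' LPC of order 8 is solved (Levinson-Durbin normal equations) and the roots
#' of the prediction polynomial give candidate resonances
#' `f = angle * fs / (2 pi)` with bandwidth `-(fs / pi) * log|root|`.
#' Candidates with 90 < f < 4000 Hz and bandwidth below `bw_max` are kept;
#' the
#' three lowest per frame, aggregated by the median over frames, are
#' reported as F1-F3. The default bandwidth cutoff of 600 Hz accommodates
#' the bandwidth inflation of low-order LPC on low-pitched voices, whose
#' second-formant pole otherwise drops out of a large share of frames.
#'
#' @param seg A `vowel_segment` (10 kHz).
#' @param order LPC order (default 8).
#' @param preemphasis Pre-emphasis coefficient (default 0.97).
#' @param bw_max Candidate bandwidth cutoff, Hz (default 600).
#' @return Named numeric `c(F1, F2, F3)` in Hz; all `NA` (with a warning)
#'   when fewer than three candidates survive in more than half the frames.
#' @export
estimate_formants <- function(seg, order = 8, preemphasis = 0.97,
                              bw_max = 600) {
  .seg_check(seg)
  fs <- seg$sample_rate
  x <- seg$samples
  x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  win <- round(0.02 * fs)
  hop <- round(0.01 * fs)
  w <- .hamming(win)
  starts <- seq(1, length(x) - win + 1, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + win - 1)] * w, numeric(win))
  per_frame <- matrix(NA_real_, 3, length(starts))
  for (i in seq_along(starts)) {
    fr <- frames[, i]
    r <- vapply(0:order, function(k)
      sum(fr[1:(win - k)] * fr[(1 + k):win]), numeric(1))
    if (r[1] <= 1e-20) next
    a <- tryCatch(solve(stats::toeplitz(r[1:order]), r[2:(order + 1)]),
                  error = function(e) NULL)
    if (is.null(a)) next
    rt <- polyroot(c(-rev(a), 1))
    mod <- Mod(rt); ang <- Arg(rt)
    keep <- ang > 0 & mod < 1
    f <- ang[keep] * fs / (2 * pi)
    bw <- -(fs / pi) * log(mod[keep])
    ok <- f > 90 & f < 4000 & bw < bw_max
    f <- sort(f[ok])
    if (length(f) >= 3) per_frame[, i] <- f[1:3]
  }
  good <- colSums(is.na(per_frame)) == 0
  if (mean(good) < 0.5) {
    warning("estimate_formants: fewer than three stable formants in most frames")
    return(c(F1 = NA_real_, F2 = NA_real_, F3 = NA_real_))
  }
  out <- apply(per_frame[, good, drop = FALSE], 1, stats::median)
  c(F1 = out[1], F2 = out[2], F3 = out[3])
}

#' Welch power spectral density
#'
#' 20 ms Hamming windows zero-padded to 512 FFT points with 90% overlap
#' (hop of 20 samples at 10 kHz), averaged one-sided modified periodograms.
#' The density integrates to the signal variance (Parseval).
#'
#' @param seg A `vowel_segment` (10 kHz).
#' @param nfft FFT length (default 512).
#' @param window_s Window length, seconds (default 0.02).
#' @param overlap Fractional window overlap (default 0.9).
#' @return A list of class `welch_psd` with `freq` (Hz), `density`
#'   (power per Hz), `df` (bin width, Hz) and `fs`.
#' @export
welch_psd <- function(seg, nfft = 512, window_s = 0.02, overlap = 0.9) {
  .seg_check(seg)
  fs <- seg$sample_rate
  x <- seg$samples - mean(seg$samples)
  win <- round(window_s * fs)
  hop <- max(1L, round(win * (1 - overlap)))
  w <- .hamming(win)
  starts <- seq(1, length(x) - win + 1, by = hop)
  fr <- vapply(starts, function(s) x[s:(s + win - 1)] * w, numeric(win))
  fr <- rbind(fr, matrix(0, nfft - win, length(starts)))
  P <- abs(stats::mvfft(fr))^2
  nb <- nfft / 2 + 1
  dens <- rowMeans(P[1:nb, , drop = FALSE]) / (fs * sum(w^2))
  dens[2:(nb - 1)] <- 2 * dens[2:(nb - 1)]
  structure(list(freq = (0:(nb - 1)) * fs / nfft, density = dens,
                 df = fs / nfft, fs = fs),
            class = "welch_psd")
}

#' The ten analysis bands
#'
#' The full 100-3000 Hz band, the six disjoint 500 Hz-wide sub-bands and
#' three octave-style groupings, in the fixed reporting order.
#'
#' @return data.frame with columns `low`, `high` (Hz) and `name`.
#' @export
default_bands <- function() {
  b <- rbind(c(100, 3000), c(100, 500), c(500, 1000), c(1000, 1500),
             c(1500, 2000), c(2000, 2500), c(2500, 3000),
             c(100, 1000), c(1000, 2000), c(2000, 3000))
  data.frame(low = b[, 1], high = b[, 2],
             name = paste0("b", b[, 1], "_", b[, 2]))
}

#' Band power, relative power and spectral centroid
#'
#' Band power is the PSD integrated over in-band bins (half-open
#' `[low, high)` so the six disjoint sub-bands partition 100-3000 Hz
#' exactly), reported in dB re digital full scale; relative power is the
#' fraction of total 100-3000 Hz power; the centroid is the power-weighted
#' mean frequency within the band.
#'
#' @param psd A [welch_psd()] result.
#' @param bands A band table as from [default_bands()].
#' @return List with named numeric vectors `band_power` (dB),
#'   `relative_power` (fractions) and `spectral_centroid` (Hz), one entry
#'   per band.
#' @export
band_features <- function(psd, bands = default_bands()) {
  stopifnot(inherits(psd, "welch_psd"))
  f <- psd$freq; S <- psd$density
  total <- sum(S[f >= 100 & f < 3000]) * psd$df
  if (total <= 0) stop("band_features: zero total power in 100-3000 Hz")
  bp <- rp <- sc <- setNames(numeric(nrow(bands)), bands$name)
  for (i in seq_len(nrow(bands))) {
    idx <- f >= bands$low[i] & f < bands$high[i]
    p <- sum(S[idx]) * psd$df
    bp[i] <- 10 * log10(p + 1e-30)
    rp[i] <- p / total
    sc[i] <- if (p > 0) sum(f[idx] * S[idx]) / sum(S[idx]) else NA_real_
  }
  list(band_power = bp, relative_power = rp, spectral_centroid = sc)
}

# HTK-style mel filterbank: n_mel x n_bins, unit-peak triangles
.mel_filterbank <- function(n_mel, nfft, fs, fmin = 0, fmax = fs / 2) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(fmin), mel(fmax), length.out = n_mel + 2))
  nb <- nfft / 2 + 1
  f <- (0:(nb - 1)) * fs / nfft
  fb <- matrix(0, n_mel, nb)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f - lo) / (ce - lo)
    dn <- (hi - f) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II matrix, n_out x n_in
.dct_matrix <- function(n_out, n_in) {
  D <- outer(0:(n_out - 1), seq_len(n_in) - 0.5,
             function(k, m) cos(pi * k * m / n_in)) * sqrt(2 / n_in)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Mel-frequency cepstral coefficients
#'
#' Frame-wise 13-coefficient MFCC: Hamming-windowed 512-point power
#' spectrum, 26-filter HTK mel filterbank up to Nyquist, log (floored), and
#' orthonormal DCT-II; aggregated to per-coefficient mean and standard
#' deviation over frames.
#'
#' @param seg A `vowel_segment` (10 kHz).
#' @param n_mfcc Number of coefficients kept (default 13).
#' @param n_mel Number of mel filters (default 26).
#' @param win,hop Frame length and hop in samples (defaults 200 / 100).
#' @param nfft FFT length (default 512).
#' @param log_floor Floor applied to filterbank energies before the log.
#' @return List with `mfcc_mean` and `mfcc_sd`, each length `n_mfcc`.
#' @export
mfcc_features <- function(seg, n_mfcc = 13, n_mel = 26, win = 200,
                          hop = 100, nfft = 512, log_floor = 1e-10) {
  .seg_check(seg)
  st <- .stft_power(seg$samples, seg$sample_rate, win, hop, nfft)
  fb <- .mel_filterbank(n_mel, nfft, seg$sample_rate)
  E <- log(pmax(fb %*% st$P, log_floor))
  C <- .dct_matrix(n_mfcc, n_mel) %*% E
  list(mfcc_mean = setNames(rowMeans(C), paste0("mfcc_mean_", 1:n_mfcc)),
       mfcc_sd = setNames(apply(C, 1, stats::sd), paste0("mfcc_sd_", 1:n_mfcc)))
}

#' Chroma, spectral contrast, roll-off, zero-crossing rate and
#' spectral shape
#'
#' Frame-wise features (20 ms window, 10 ms hop): chroma is the per-frame
#' distribution of spectral power over the 12 pitch classes (bins
#' 100-5000 Hz, energy fractions summing to 1 per voiced frame); contrast
#' is the peak-to-valley difference (dB, top vs bottom decile of bins) in 7
#' octave-style bands with edges 0, 100, 200, 400, 800, 1600, 3200, 5000 Hz;
#' roll-off is the frequency below which 85% of frame energy lies; ZCR is
#' sign changes per sample. Spectral skewness, kurtosis and entropy (nats)
#' are computed once from the 100-3000 Hz Welch PSD normalized to a
#' probability distribution over frequency.
#'
#' @param seg A `vowel_segment` (10 kHz).
#' @param psd The segment's [welch_psd()] (computed if missing).
#' @param rolloff Roll-off energy fraction (default 0.85).
#' @return Named list of vectors: `chroma_mean`/`chroma_sd` (12),
#'   `contrast_mean`/`contrast_sd` (7), `rolloff_mean`, `rolloff_sd`,
#'   `zcr_mean`, `zcr_sd`, `spectral_skewness`, `spectral_kurtosis`,
#'   `spectral_entropy`.
#' @export
misc_features <- function(seg, psd = welch_psd(seg), rolloff = 0.85) {
  .seg_check(seg)
  fs <- seg$sample_rate
  st <- .stft_power(seg$samples, fs, win = 200, hop = 100, nfft = 512)
  P <- st$P; f <- st$freq

  # chroma: pitch-class energy fractions
  in_rng <- f >= 100 & f < 5000
  pc <- (round(69 + 12 * log2(f[in_rng] / 440))) %% 12
  Pm <- P[in_rng, , drop = FALSE]
  ch <- matrix(0, 12, ncol(Pm))
  for (k in 0:11) ch[k + 1, ] <- colSums(Pm[pc == k, , drop = FALSE])
  tot <- colSums(ch)
  ch <- sweep(ch, 2, pmax(tot, 1e-30), "/")
  chroma_mean <- setNames(rowMeans(ch), paste0("chroma_mean_", 1:12))
  chroma_sd <- setNames(apply(ch, 1, stats::sd), paste0("chroma_sd_", 1:12))

  # spectral contrast in 7 octave-style bands
  edges <- c(0, 100, 200, 400, 800, 1600, 3200, 5000)
  ct <- matrix(NA_real_, 7, ncol(P))
  for (b in 1:7) {
    idx <- which(f >= edges[b] & f < edges[b + 1])
    db <- 10 * log10(P[idx, , drop = FALSE] + 1e-12)
    q <- max(1L, round(0.1 * length(idx)))
    ct[b, ] <- apply(db, 2, function(v) {
      sv <- sort(v)
      mean(sv[(length(sv) - q + 1):length(sv)]) - mean(sv[1:q])
    })
  }
  contrast_mean <- setNames(rowMeans(ct), paste0("contrast_mean_", 1:7))
  contrast_sd <- setNames(apply(ct, 1, stats::sd), paste0("contrast_sd_", 1:7))

  # roll-off frequency per frame
  cum <- apply(P, 2, cumsum)
  tot2 <- cum[nrow(cum), ]
  ro <- vapply(seq_len(ncol(P)), function(j) {
    if (tot2[j] <= 0) return(NA_real_)
    f[which(cum[, j] >= rolloff * tot2[j])[1]]
  }, numeric(1))
  ro <- ro[is.finite(ro)]

  # zero-crossing rate per frame (crossings per sample)
  x <- seg$samples
  starts <- seq(1, length(x) - 200 + 1, by = 100)
  zc <- vapply(starts, function(s) {
    fr <- x[s:(s + 199)]
    mean(fr[-length(fr)] * fr[-1] < 0)
  }, numeric(1))

  # spectral shape from the normalized 100-3000 Hz PSD
  idx <- psd$freq >= 100 & psd$freq < 3000
  p <- psd$density[idx] / sum(psd$density[idx])
  fv <- psd$freq[idx]
  mu <- sum(fv * p)
  sig <- sqrt(sum((fv - mu)^2 * p))
  pn <- p[p > 0]

  c(list(chroma_mean = chroma_mean, chroma_sd = chroma_sd,
         contrast_mean = contrast_mean, contrast_sd = contrast_sd),
    list(rolloff_mean = mean(ro), rolloff_sd = if (length(ro) > 1) sd(ro) else 0,
         zcr_mean = mean(zc), zcr_sd = if (length(zc) > 1) sd(zc) else 0,
         spectral_skewness = sum(((fv - mu) / sig)^3 * p),
         spectral_kurtosis = sum(((fv - mu) / sig)^4 * p),
         spectral_entropy = -sum(pn * log(pn))))
}

#' Names of the 106 features, in reporting order
#'
#' The fixed inventory: pitch mean/sd (2), F1-F3 (3), band power (10),
#' relative power (10), spectral centroid (10), MFCC mean (13) and sd (13),
#' chroma mean (12) and sd (12), contrast mean (7) and sd (7), roll-off
#' mean/sd (2), ZCR mean/sd (2), spectral skewness, kurtosis, entropy (3).
#'
#' @param bands Band table used for the band-feature names.
#' @return Character vector of length 106.
#' @export
feature_names <- function(bands = default_bands()) {
  c("pitch_mean", "pitch_sd", "F1", "F2", "F3",
    paste0("band_power_", bands$name),
    paste0("relative_power_", bands$name),
    paste0("spectral_centroid_", bands$name),
    paste0("mfcc_mean_", 1:13), paste0("mfcc_sd_", 1:13),
    paste0("chroma_mean_", 1:12), paste0("chroma_sd_", 1:12),
    paste0("contrast_mean_", 1:7), paste0("contrast_sd_", 1:7),
    "rolloff_mean", "rolloff_sd", "zcr_mean", "zcr_sd",
    "spectral_skewness", "spectral_kurtosis", "spectral_entropy")
}

#' Extract the full 106-scalar feature vector
#'
#' Runs every feature family on one preprocessed segment and assembles the
#' fixed-order vector. Missing-value sentinels from the pitch and formant
#' estimators are propagated, never imputed.
#'
#' @param seg A `vowel_segment` (10 kHz, >= 0.2 s).
#' @param bands Band table (default [default_bands()]).
#' @return Named numeric vector of length 106 in [feature_names()] order.
#' @export
extract_all <- function(seg, bands = default_bands()) {
  .seg_check(seg)
  id <- paste0(seg$participant_id %||% "?", "/", seg$vowel %||% "?")
  out <- tryCatch({
    psd <- welch_psd(seg)
    v <- c(estimate_pitch(seg), estimate_formants(seg),
           unlist(band_features(psd, bands), use.names = FALSE),
           unlist(mfcc_features(seg), use.names = FALSE),
           unlist(misc_features(seg, psd), use.names = FALSE))
    names(v) <- feature_names(bands)
    v
  }, error = function(e) stop("extract_all [", id, "]: ", conditionMessage(e)))
  stopifnot(length(out) == 106L)
  out
}

#' Extract features for a list of segments into a tidy table
#'
#' @param segments List of `vowel_segment` objects (e.g. preprocessed
#'   output of [read_segments()]); `NULL` entries are skipped.
#' @param bands Band table.
#' @return data.frame with `participant_id`, `vowel` and the 106 feature
#'   columns in fixed order.
#' @export
extract_features <- function(segments, bands = default_bands()) {
  segments <- Filter(Negate(is.null), segments)
  rows <- lapply(segments, function(s)
    cbind(data.frame(participant_id = s$participant_id, vowel = s$vowel),
          as.data.frame(t(extract_all(s, bands)))))
  do.call(rbind, rows)
}
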