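#' Slice labelled vowel segments out of a recording
#'
#' Reads a WAV recording and its PRAAT TextGrid annotation and returns one
#' raw segment per labelled interval of the requested tier, sliced half-open
#' `[start, end)` in samples. Empty-label intervals (silence) are skipped.
#'
#' @param audio Path to a WAV file.
#' @param annotations Path to the matching TextGrid.
#' @param tier Interval tier holding the vowel labels (default `"vowel"`).
#' @param participant_id Identifier attached to each segment; defaults to
#'   the audio file name without extension (with any `_<vowel>` suffix kept).
#' @return List of raw segments: each a list with `participant_id`, `vowel`,
#'   `samples`, `sample_rate`, `source_span` (start/end seconds).
#' @export
read_segments <- function(audio, annotations, tier = "vowel",
                          participant_id = NULL) {
  wav <- read_wav(audio)
  tg <- read_textgrid(annotations)
  if (!tier %in% names(tg))
    stop("read_segments: tier '", tier, "' not found in ", annotations)
  iv <- tg[[tier]]
  iv <- iv[nzchar(trimws(iv$label)), , drop = FALSE]
  if (nrow(iv) == 0) {
    warning("read_segments: no labelled intervals in tier '", tier, "' of ",
            annotations)
    return(list())
  }
  bad <- !iv$label %in% c("i", "u", "a", "e", "o")
  if (any(bad))
    stop("read_segments: unknown vowel label(s): ",
         paste(sprintf("'%s' [%.3f-%.3f s]", iv$label[bad], iv$xmin[bad],
                       iv$xmax[bad]), collapse = ", "))
  iv <- iv[order(iv$xmin), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-9))
    stop("read_segments: overlapping intervals in tier '", tier, "'")
  if (is.null(participant_id))
    participant_id <- tools::file_path_sans_ext(basename(audio))
  fs <- wav$sample_rate
  n <- length(wav$samples)
  lapply(seq_len(nrow(iv)), function(k) {
    # small epsilon keeps boundaries that are exact sample times stable
    # against floating-point representation of the interval endpoints
    i0 <- floor(iv$xmin[k] * fs + 1e-6) + 1
    i1 <- floor(iv$xmax[k] * fs + 1e-6)  # half-open [start, end)
    if (i1 > n)
      stop(sprintf(
        "read_segments: interval '%s' [%.3f-%.3f s] extends past audio end (%.3f s)",
        iv$label[k], iv$xmin[k], iv$xmax[k], n / fs))
    list(participant_id = participant_id, vowel = iv$label[k],
         samples = wav$samples[i0:i1], sample_rate = fs,
         source_span = c(iv$xmin[k], iv$xmax[k]))
  })
}

#' Downsample and band-pass filter a vowel segment
#'
#' Resamples to 10,000 Hz (polyphase rational resampling) and applies a
#' 5th-order Butterworth band-pass between 100 and 3000 Hz. The filter is
#' applied forward-backward (zero phase) so segment-internal timing is
#' preserved for framing; only spectral magnitudes are used downstream.
#'
#' @param seg A raw segment from [read_segments()], or any list with
#'   `samples` and `sample_rate`.
#' @param min_duration Segments shorter than this (s) after resampling are
#'   rejected with a warning and `NULL` is returned; stable frame statistics
#'   need at least ~10 20-ms frames.
#' @return A list of class `vowel_segment` with `samples` (10 kHz),
#'   `sample_rate = 10000` and the pass-through identification fields, or
#'   `NULL` for too-short segments.
#' @export
preprocess_segment <- function(seg, min_duration = 0.2) {
  fs <- seg$sample_rate
  if (fs < 6000)
    stop("preprocess_segment: input sample rate ", fs,
         " Hz too low (need >= 6000 Hz for the 3 kHz band edge)")
  x <- as.numeric(seg$samples)
  if (anyNA(x)) stop("preprocess_segment: NaN samples in input")
  target <- 10000
  if (fs != target) {
    g <- .gcd(target, round(fs))
    x <- as.numeric(signal::resample(x, target / g, round(fs) / g))
  }
  if (length(x) / target < min_duration) {
    warning(sprintf(
      "preprocess_segment: segment '%s/%s' too short (%.3f s < %.2f s); dropped",
      seg$participant_id %||% "?", seg$vowel %||% "?",
      length(x) / target, min_duration))
    return(NULL)
  }
  bf <- signal::butter(5, c(100, 3000) / (target / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  structure(list(participant_id = seg$participant_id, vowel = seg$vowel,
                 samples = y, sample_rate = target,
                 source_span = seg$source_span),
            class = "vowel_segment")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

`%||%` <- function(a, b) if (is.null(a)) b else a
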