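#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file containing integer PCM samples (8/16/32 bit) or
#' IEEE float samples. Only the first channel is returned; amplitudes are
#' scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `samples` (numeric vector in \[-1, 1\]) and
#'   `sample_rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      bytes_per <- fmt$bits / 8
      n <- size / bytes_per
      if (fmt$audio_format == 3L) {
        x <- readBin(con, "double", n, bytes_per, endian = "little")
      } else if (fmt$bits == 8L) {
        x <- (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 127
      } else {
        x <- readBin(con, "integer", n, bytes_per, signed = TRUE, endian = "little") /
          (2^(fmt$bits - 1) - 1)
      }
      if (fmt$n_channels > 1L) x <- x[seq(1, length(x), by = fmt$n_channels)]
      samples <- x
      break
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word aligned)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = as.numeric(samples), sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\] (values are
#'   clipped to that range before quantization).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
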