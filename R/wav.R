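#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit PCM). Samples are scaled by the
#' maximum absolute amplitude so the full int16 range is used; an all-zero
#' waveform is written as digital silence.
#'
#' @param wave A `"waveform"` (list with `samples`, `rate`) as produced by
#'   [synthesize_vocalization()], or a numeric vector (then `rate` must be
#'   given).
#' @param path Output file path.
#' @param rate Sampling rate in Hz when `wave` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, rate = NULL) {
  if (inherits(wave, "waveform")) {
    samples <- wave$samples
    rate <- wave$rate
  } else {
    samples <- as.numeric(wave)
    if (is.null(rate)) stop("`rate` required when `wave` is a bare vector")
  }
  peak <- max(abs(samples))
  scaled <- if (peak > 0) samples / peak else samples
  pcm <- as.integer(round(scaled * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Reads 16- or 24-bit PCM WAV; stereo is averaged to mono. Samples are
#' returned on \[-1, 1\].
#'
#' @param path Path to a WAV file.
#' @return A `"waveform"` list with `samples` and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  channels <- rate <- bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little") # byte rate
      readBin(con, "integer", size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (bits == 16L) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32768
      } else if (bits == 24L) {
        raw <- as.integer(readBin(con, "raw", n = size))
        b1 <- raw[seq(1, length(raw), 3)]
        b2 <- raw[seq(2, length(raw), 3)]
        b3 <- raw[seq(3, length(raw), 3)]
        v <- b1 + 256 * b2 + 65536 * b3
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else {
        stop("unsupported bit depth: ", bits)
      }
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (channels > 1L) {
    m <- matrix(samples, nrow = channels)
    samples <- colMeans(m)
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}
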