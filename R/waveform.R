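#' Construct a waveform object
#'
#' A waveform is the package's representation of mono audio: a numeric vector
#' of samples normalized to `[-1, 1]` plus a sample rate in Hz.
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`; must be finite.
#' @param sample_rate sampling rate in Hz (positive).
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 350 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a positive scalar", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.2f s), peak %.3f>\n",
              length(x$samples), x$sample_rate, duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a [waveform].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate
}

#' Read a mono RIFF WAV file
#'
#' Reads uncompressed PCM WAV (8, 16, 24 or 32 bit integer, or 32-bit float).
#' Multichannel files are mixed down to mono by averaging; samples are
#' normalized to `[-1, 1]`.
#'
#' @param path file path.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, integer(), 1, 4, endian = "little") # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, raw(), size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), size)
    } else {
      readBin(con, raw(), size + size %% 2) # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt/data chunk in ", path, call. = FALSE)

  n_bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% n_bytes
  x <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, numeric(), n, size = 4, endian = "little")
  } else if (fmt$bits == 8) {
    (as.integer(data_raw) - 128) / 128 # 8-bit PCM is unsigned
  } else if (fmt$bits == 16) {
    # divide by 32767 so 16-bit PCM survives a write/read cycle exactly
    readBin(data_raw, integer(), n, size = 2, signed = TRUE,
            endian = "little") / 32767
  } else if (fmt$bits == 24) {
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$bits == 32) {
    readBin(data_raw, integer(), n, size = 4, endian = "little") / 2147483648
  } else stop("unsupported bit depth: ", fmt$bits, call. = FALSE)

  if (fmt$n_channels > 1)
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  waveform(pmin(pmax(x, -1), 1), fmt$sample_rate)
}

#' Write a waveform as a mono 16-bit PCM WAV file
#'
#' @param w a [waveform]; samples are clipped to `[-1, 1]` before quantizing.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmin(pmax(w$samples, -1), 1) * 32767))
  n_data <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  sr <- as.integer(round(w$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
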