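#' Split a waveform into consecutive 100 ms analysis frames
#'
#' Frames are non-overlapping, rectangular, and `round(frame_ms * rate / 1000)`
#' samples long; a trailing partial frame is dropped. This is the framing used
#' by every meter in the package, so VU, PPM and spectrum traces computed from
#' the same waveform always have the same number of frames.
#'
#' @param w a [waveform].
#' @param frame_ms frame length in milliseconds (default 100).
#' @return A numeric matrix with one frame per row (`n_frames x frame_len`);
#'   zero rows when the signal is shorter than one frame.
#' @export
frame_signal <- function(w, frame_ms = 100) {
  stopifnot(inherits(w, "waveform"))
  if (!is.numeric(frame_ms) || frame_ms <= 0)
    stop("frame_ms must be positive", call. = FALSE)
  flen <- round(frame_ms * w$sample_rate / 1000)
  if (flen < 1) stop("frame shorter than one sample", call. = FALSE)
  n_frames <- length(w$samples) %/% flen
  if (n_frames == 0) return(matrix(numeric(0), nrow = 0, ncol = flen))
  m <- matrix(w$samples[seq_len(n_frames * flen)], ncol = flen, byrow = TRUE)
  m
}

new_meter_trace <- function(values, kind, frame_ms) {
  structure(list(values = as.numeric(values), kind = kind,
                 frame_ms = frame_ms),
            class = "meter_trace")
}

#' @export
print.meter_trace <- function(x, ...) {
  cat(sprintf("<%s trace: %d frames x %g ms, range [%.1f, %.1f] U>\n",
              x$kind, length(x$values), x$frame_ms,
              if (length(x$values)) min(x$values) else NA,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

# Per-frame PCM magnitudes used by both meters: |round(x * 32767)|.
frame_pcm_abs <- function(w, frame_ms) {
  m <- frame_signal(w, frame_ms)
  abs(round(m * U_FULL_SCALE))
}

#' Volume-unit (VU) trace: mean intensity per 100 ms
#'
#' The VU meter reports, for every consecutive 100 ms frame, the mean of the
#' absolute 16-bit PCM sample magnitudes, in the app's "U" units
#' (`U = |round(sample * 32767)|`, so a full-scale signal meters 32767 U).
#'
#' @param w a [waveform].
#' @param frame_ms frame length in milliseconds.
#' @return A `meter_trace` with `kind = "VU"`.
#' @seealso [compute_ppm()], [summarize_trace()]
#' @export
compute_vu <- function(w, frame_ms = 100) {
  u <- frame_pcm_abs(w, frame_ms)
  new_meter_trace(if (nrow(u)) rowMeans(u) else numeric(0), "VU", frame_ms)
}

#' Peak-programme (PPM) trace: maximum intensity per 100 ms
#'
#' Per 100 ms frame, the maximum absolute 16-bit PCM sample magnitude in U.
#' By construction every PPM frame value is >= the VU value of the same frame.
#'
#' @inheritParams compute_vu
#' @return A `meter_trace` with `kind = "PPM"`.
#' @export
compute_ppm <- function(w, frame_ms = 100) {
  u <- frame_pcm_abs(w, frame_ms)
  vals <- if (nrow(u)) apply(u, 1, max) else numeric(0)
  new_meter_trace(vals, "PPM", frame_ms)
}

#' Short-time magnitude spectrum series
#'
#' Per 100 ms frame: Hann-windowed, zero-padded FFT magnitude up to Nyquist,
#' scaled so that a full-scale sinusoid peaks near 32767 U (the same unit
#' scale as the meters).
#'
#' @inheritParams compute_vu
#' @param fft_size FFT length; must be >= the frame length in samples.
#' @return A `spectrum_series`: list with `magnitude` (frames x bins matrix in
#'   U), `bin_width` (Hz), `frame_ms`, `freqs` (bin centre frequencies, Hz).
#' @export
compute_spectrum <- function(w, frame_ms = 100, fft_size = 4096) {
  m <- frame_signal(w, frame_ms)
  flen <- ncol(m)
  if (fft_size < flen)
    stop("fft_size must be >= frame length (", flen, ")", call. = FALSE)
  n_bins <- fft_size %/% 2 + 1
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1)) # Hann
  # a full-scale sine under a Hann window has peak-bin magnitude ~ flen / 4
  scale <- U_FULL_SCALE / (sum(win) / 2)
  mag <- matrix(0, nrow = nrow(m), ncol = n_bins)
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      x <- c(m[i, ] * win, numeric(fft_size - flen))
      mag[i, ] <- Mod(stats::fft(x))[seq_len(n_bins)] * scale
    }
  }
  structure(list(magnitude = mag,
                 bin_width = w$sample_rate / fft_size,
                 frame_ms = frame_ms,
                 freqs = (seq_len(n_bins) - 1) * w$sample_rate / fft_size),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum series: %d frames x %d bins, bin width %.2f Hz>\n",
              nrow(x$magnitude), ncol(x$magnitude), x$bin_width))
  invisible(x)
}

#' Default voice-activity threshold for a VU trace
#'
#' `max(floor_u, rel * max(trace))`: an absolute floor of 50 U (below typical
#' room noise at 16-bit scale) or 5% of the trace maximum, whichever is
#' larger.
#'
#' @param vu a VU `meter_trace` or numeric vector of U values.
#' @param floor_u absolute floor in U.
#' @param rel relative fraction of the trace maximum.
#' @return Threshold in U.
#' @export
default_activity_threshold <- function(vu, floor_u = 50, rel = 0.05) {
  v <- if (inherits(vu, "meter_trace")) vu$values else vu
  if (!length(v)) return(floor_u)
  max(floor_u, rel * max(v))
}

#' Autocorrelation fundamental-frequency track
#'
#' Per 100 ms frame: frames whose VU value exceeds the activity threshold are
#' taken as voiced and F0 is estimated as the frequency of the largest
#' autocorrelation peak with lag restricted to the search band, refined by
#' parabolic interpolation. Unvoiced frames are `NA`.
#'
#' @param w a [waveform].
#' @param band two-element numeric, F0 search band in Hz (default
#'   `c(150, 800)`, bracketing the 250-450 Hz band of healthy newborns).
#' @param frame_ms frame length in milliseconds.
#' @param activity_threshold voicing threshold in U; `NULL` for the default
#'   rule of [default_activity_threshold()].
#' @return An `f0_track`: list with `f0` (Hz per frame, `NA` = unvoiced),
#'   `band`, `frame_ms`.
#' @export
estimate_f0 <- function(w, band = c(150, 800), frame_ms = 100,
                        activity_threshold = NULL) {
  sr <- w$sample_rate
  if (band[1] <= 0 || band[2] >= sr / 2 || band[1] >= band[2])
    stop("band must lie within (0, Nyquist)", call. = FALSE)
  m <- frame_signal(w, frame_ms)
  vu <- compute_vu(w, frame_ms)
  thr <- activity_threshold %||% default_activity_threshold(vu)
  lag_min <- max(2L, floor(sr / band[2]))
  lag_max <- ceiling(sr / band[1])
  f0 <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (vu$values[i] <= thr) next
    x <- m[i, ] - mean(m[i, ])
    n <- length(x)
    if (lag_max >= n) next
    r <- vapply(lag_min:lag_max, function(L) {
      sum(x[seq_len(n - L)] * x[(L + 1):n])
    }, numeric(1))
    k <- which.max(r)
    lag <- (lag_min:lag_max)[k]
    # parabolic refinement around the peak lag
    if (k > 1 && k < length(r)) {
      denom <- r[k - 1] - 2 * r[k] + r[k + 1]
      if (denom < 0) lag <- lag + 0.5 * (r[k - 1] - r[k + 1]) / denom
    }
    f0[i] <- sr / lag
  }
  structure(list(f0 = f0, band = band, frame_ms = frame_ms),
            class = "f0_track")
}

#' @export
print.f0_track <- function(x, ...) {
  v <- x$f0[!is.na(x$f0)]
  cat(sprintf("<f0 track: %d frames, %d voiced, median %.1f Hz>\n",
              length(x$f0), length(v), if (length(v)) stats::median(v) else NA))
  invisible(x)
}

#' Summarize a meter or spectrum trace
#'
#' Mean, minimum, maximum and frame count of a trace. With
#' `voiced_only = TRUE` (the default mirrors whole-recording cry-intensity
#' statistics) only frames above the activity threshold are summarized, so
#' that minima describe the quietest cry-active frame rather than silence.
#' For a spectrum series the per-frame scalar is the maximum bin magnitude
#' (peak spectral intensity); voicing is always decided on a VU trace.
#'
#' @param t a `meter_trace` or `spectrum_series`.
#' @param voiced_only summarize only voiced (cry-active) frames?
#' @param activity_threshold threshold in U (`NULL` = default rule applied to
#'   `vu`, or to `t` itself when `t` is a VU trace).
#' @param vu VU trace used to decide voicing when `t` is not itself VU.
#' @return A `trace_summary`: list with `mean`, `min`, `max`, `n_frames`.
#' @export
summarize_trace <- function(t, voiced_only = TRUE, activity_threshold = NULL,
                            vu = NULL) {
  vals <- if (inherits(t, "spectrum_series")) {
    if (nrow(t$magnitude)) apply(t$magnitude, 1, max) else numeric(0)
  } else if (inherits(t, "meter_trace")) {
    t$values
  } else stop("t must be a meter_trace or spectrum_series", call. = FALSE)
  if (!length(vals)) stop("empty trace", call. = FALSE)

  if (voiced_only) {
    vu_vals <- if (!is.null(vu)) {
      if (inherits(vu, "meter_trace")) vu$values else vu
    } else if (inherits(t, "meter_trace") && t$kind == "VU") {
      t$values
    } else stop("voiced_only summary of a non-VU trace needs `vu`",
                call. = FALSE)
    if (length(vu_vals) != length(vals))
      stop("vu trace and t have different frame counts", call. = FALSE)
    thr <- activity_threshold %||% default_activity_threshold(vu_vals)
    vals <- vals[vu_vals > thr]
    if (!length(vals)) stop("no voiced frames in trace", call. = FALSE)
  }
  structure(list(mean = mean(vals), min = min(vals), max = max(vals),
                 n_frames = length(vals)),
            class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("<trace summary: mean %.3f U (%.0f-%.0f U), %d frames>\n",
              x$mean, x$min, x$max, x$n_frames))
  invisible(x)
}
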