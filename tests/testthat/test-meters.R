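sine_wave <- function(freq, amp = 1, dur = 1, sr = 22050) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)[-1]), sr)
}

test_that("framing: exact division, truncation, sub-frame input", {
  w <- waveform(rep(0.1, 1000), 1000)
  expect_equal(dim(frame_signal(w, 100)), c(10, 100))
  w2 <- waveform(rep(0.1, 1050), 1000)
  expect_equal(nrow(frame_signal(w2, 100)), 10)   # 50 samples dropped
  w3 <- waveform(rep(0.1, 50), 1000)
  expect_equal(nrow(frame_signal(w3, 100)), 0)
})

test_that("VU and PPM constants: silence and full scale", {
  sil <- waveform(rep(0, 2000), 1000)
  expect_true(all(compute_vu(sil)$values == 0))
  expect_true(all(compute_ppm(sil)$values == 0))
  full <- waveform(rep(1, 2000), 1000)
  expect_true(all(compute_vu(full)$values == 32767))
  expect_true(all(compute_ppm(full)$values == 32767))
})

test_that("VU of a unit sine matches the rectified-mean value 2/pi * 32767", {
  w <- sine_wave(350)
  vu <- compute_vu(w)
  expect_equal(length(vu$values), 10)
  expect_equal(vu$values, rep(2 / pi * 32767, 10), tolerance = 0.01)
})

test_that("PPM of a half-scale sine meters half scale; PPM >= VU always", {
  w <- sine_wave(350, amp = 0.5)
  ppm <- compute_ppm(w)
  expect_equal(ppm$values, rep(16384, 10), tolerance = 0.01)
  set.seed(1)
  for (i in 1:10) {
    x <- waveform(stats::runif(1500, -1, 1) * stats::runif(1), 1000)
    expect_true(all(compute_ppm(x)$values >= compute_vu(x)$values))
  }
})

test_that("meters agree exactly with a naive two-loop reference", {
  naive_meter <- function(samples, sr, frame_ms, fun) {
    flen <- round(frame_ms * sr / 1000)
    n_frames <- length(samples) %/% flen
    out <- numeric(n_frames)
    for (f in seq_len(n_frames)) {
      acc <- numeric(flen)
      for (j in seq_len(flen))
        acc[j] <- abs(round(samples[(f - 1) * flen + j] * 32767))
      out[f] <- fun(acc)
    }
    out
  }
  set.seed(42)
  for (i in 1:100) {
    sr <- sample(c(800, 1000, 4000), 1)
    n <- sample(150:900, 1)
    x <- stats::runif(n, -1, 1)
    w <- waveform(x, sr)
    expect_identical(compute_vu(w)$values, naive_meter(x, sr, 100, mean))
    expect_identical(compute_ppm(w)$values, naive_meter(x, sr, 100, max))
  }
})

test_that("scaling samples scales both meters within rounding", {
  set.seed(7)
  x <- stats::runif(4000, -1, 1)
  w <- waveform(x, 2000)
  for (c in c(0.1, 0.37, 0.8)) {
    wc <- waveform(c * x, 2000)
    expect_lt(max(abs(compute_vu(wc)$values - c * compute_vu(w)$values)), 1)
    expect_lt(max(abs(compute_ppm(wc)$values - c * compute_ppm(w)$values)), 1)
  }
})

test_that("VU, PPM and spectrum share the frame count", {
  w <- sine_wave(300, dur = 1.234, sr = 8000)
  vu <- compute_vu(w); ppm <- compute_ppm(w)
  sp <- compute_spectrum(w, fft_size = 1024)
  expect_equal(length(vu$values), length(ppm$values))
  expect_equal(length(vu$values), nrow(sp$magnitude))
})

test_that("spectrum: silence is zero; tones peak at their bins", {
  sil <- waveform(rep(0, 22050), 22050)
  expect_true(all(compute_spectrum(sil)$magnitude == 0))

  w <- sine_wave(350)
  sp <- compute_spectrum(w)
  for (f in seq_len(nrow(sp$magnitude))) {
    peak <- sp$freqs[which.max(sp$magnitude[f, ])]
    expect_lte(abs(peak - 350), sp$bin_width)
  }
  # full-scale sine peaks near full scale in U
  expect_equal(max(sp$magnitude), 32767, tolerance = 0.05)

  two <- waveform(0.5 * sin(2 * pi * 300 * (1:22050) / 22050) +
                    0.5 * sin(2 * pi * 600 * (1:22050) / 22050), 22050)
  sp2 <- compute_spectrum(two)
  m <- colMeans(sp2$magnitude)
  near <- function(hz) which(abs(sp2$freqs - hz) <= sp2$bin_width)
  top2 <- order(m, decreasing = TRUE)[1:8]
  expect_true(any(top2 %in% near(300)))
  expect_true(any(top2 %in% near(600)))
})

test_that("F0 tracking: harmonic stack, silence, healthy preset band", {
  spec <- synth_spec(noise_rms = 0, f0_jitter = 0, f0_mean = 350)
  script <- structure(list(
    words = data.frame(phrase = 0L, sentence = 0L, word = 0L, onset = 0,
                       duration = 1.5, level_u = NA_real_,
                       peak_amplitude = 0.6, f0 = 350),
    total_duration = 1.5), class = "cry_script")
  w <- render_cry(script, spec)
  f0 <- estimate_f0(w)
  voiced <- f0$f0[!is.na(f0$f0)]
  expect_gt(length(voiced), 10)
  expect_true(all(abs(voiced - 350) <= 5))

  sil <- waveform(rep(0, 44100), 22050)
  expect_true(all(is.na(estimate_f0(sil)$f0)))

  # healthy-newborn preset: median voiced F0 inside 250-450 Hz
  spec_h <- quick_spec("M")
  sc <- plan_cry(spec_h, 2)
  wh <- render_cry(sc, spec_h)
  fh <- estimate_f0(wh)
  expect_true(stats::median(fh$f0, na.rm = TRUE) >= 250)
  expect_true(stats::median(fh$f0, na.rm = TRUE) <= 450)
})

test_that("trace summaries: arithmetic, degenerate frame, ordering, errors", {
  tr <- structure(list(values = c(10, 20, 30), kind = "VU", frame_ms = 100),
                  class = "meter_trace")
  s <- summarize_trace(tr, voiced_only = FALSE)
  expect_equal(c(s$mean, s$min, s$max, s$n_frames), c(20, 10, 30, 3))

  one <- structure(list(values = 7, kind = "VU", frame_ms = 100),
                   class = "meter_trace")
  s1 <- summarize_trace(one, voiced_only = FALSE)
  expect_equal(c(s1$mean, s1$min, s1$max), c(7, 7, 7))

  empty <- structure(list(values = numeric(0), kind = "VU", frame_ms = 100),
                     class = "meter_trace")
  expect_error(summarize_trace(empty), "empty")

  set.seed(3)
  for (i in 1:20) {
    tr <- structure(list(values = stats::runif(50, 0, 32767), kind = "VU",
                         frame_ms = 100), class = "meter_trace")
    s <- summarize_trace(tr, voiced_only = (i %% 2 == 0))
    expect_lte(s$min, s$mean)
    expect_lte(s$mean, s$max)
  }
})
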