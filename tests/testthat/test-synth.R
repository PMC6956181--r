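test_that("degenerate ranges force the scripted hierarchy exactly", {
  sc <- plan_cry(fixed_structure_spec(), 11)
  cnt <- script_counts(sc)
  expect_equal(cnt$words, 6L)
  expect_equal(cnt$sentences, 2L)
  expect_equal(cnt$phrases, 1L)
  # gaps between words in a sentence equal the configured inhalation gap
  w <- sc$words[sc$words$sentence == 0, ]
  gaps <- w$onset[-1] - (w$onset[-3] + w$duration[-3])
  expect_equal(gaps, rep(0.3, 2), tolerance = 1e-9)
})

test_that("a sub-word duration budget yields one truncated word", {
  spec <- fixed_structure_spec(total_duration_range = c(0.5, 0.5),
                               word_duration_mean = 1,
                               word_duration_range = c(1, 1),
                               first_word_duration_mean = 1)
  sc <- plan_cry(spec, 5)
  expect_equal(nrow(sc$words), 1L)
  expect_equal(sc$words$duration, 0.5, tolerance = 1e-9)
  expect_equal(sc$total_duration, 0.5, tolerance = 1e-9)
})

test_that("invalid specs fail naming the violated invariant", {
  expect_error(synth_spec(intra_sentence_gap = 2, inter_sentence_pause = 1),
               "intra_sentence_gap < inter_sentence_pause")
  expect_error(synth_spec(word_duration_range = c(0.01, 1)), "0.1 s")
  expect_error(synth_spec(f0_mean = 100), "f0_mean")
  expect_error(synth_spec(amplitude_min_mean = 50000), "amplitude_min_mean")
  expect_error(synth_spec(total_duration_range = c(10, 5)),
               "total_duration_range")
})

test_that("words-per-sentence sampler recovers its own parameters (group M)", {
  # Monte-Carlo over planned scripts: pool >= 1000 sentences
  spec <- cry_preset("M", word_duration_range = c(0.5, 0.5),
                     word_duration_mean = 0.5, first_word_duration_mean = 0.5,
                     first_word_duration_sd = 0.1,
                     total_duration_range = c(80, 90), noise_rms = 0)
  wps <- integer(0)
  i <- 0
  while (length(wps) < 1000) {
    i <- i + 1
    sc <- plan_cry(spec, 1000 + i)
    wps <- c(wps, as.integer(table(paste(sc$words$phrase,
                                         sc$words$sentence))))
  }
  expect_equal(mean(wps), 9.45, tolerance = 0.3 / 9.45)
  expect_gte(min(wps), 4)
  expect_lte(max(wps), 18)
})

test_that("script invariants hold: time order, no overlap, contiguous ids", {
  for (seed in 1:5) {
    sc <- plan_cry(quick_spec(), seed)
    w <- sc$words
    expect_true(all(diff(w$onset) > 0))
    expect_true(all(w$onset[-1] >= (w$onset + w$duration)[-nrow(w)] - 1e-9))
    expect_lte(max(w$onset + w$duration), sc$total_duration + 1e-9)
    # (phrase, sentence) pairs contiguous from 0
    expect_equal(sort(unique(w$phrase)), seq_len(max(w$phrase) + 1) - 1L)
    for (ph in unique(w$phrase)) {
      s <- w$sentence[w$phrase == ph]
      expect_equal(sort(unique(s)), seq_len(max(s) + 1) - 1L)
      for (se in unique(s)) {
        wi <- w$word[w$phrase == ph & w$sentence == se]
        expect_equal(wi, seq_along(wi) - 1L)
      }
    }
  }
})

test_that("an empty script renders to silence of the requested length", {
  empty <- structure(list(
    words = data.frame(phrase = integer(0), sentence = integer(0),
                       word = integer(0), onset = numeric(0),
                       duration = numeric(0), level_u = numeric(0),
                       peak_amplitude = numeric(0), f0 = numeric(0)),
    total_duration = 1.3), class = "cry_script")
  spec <- quick_spec(noise_rms = 0)
  w <- render_cry(empty, spec)
  expect_equal(length(w$samples), round(1.3 * spec$sample_rate))
  expect_true(all(w$samples == 0))
})

test_that("a rendered word peaks at its scripted amplitude and frequency", {
  spec <- synth_spec(noise_rms = 0, f0_jitter = 0)
  script <- structure(list(
    words = data.frame(phrase = 0L, sentence = 0L, word = 0L,
                       onset = 0, duration = 1, level_u = NA_real_,
                       peak_amplitude = 0.5, f0 = 350),
    total_duration = 1), class = "cry_script")
  w <- render_cry(script, spec)
  expect_equal(max(abs(w$samples)), 0.5, tolerance = 1e-3)
  ppm <- compute_ppm(w)
  expect_equal(max(ppm$values), 0.5 * 32767, tolerance = 0.01)
  # dominant spectral component at the scripted F0
  sp <- compute_spectrum(w)
  peak_hz <- sp$freqs[which.max(colMeans(sp$magnitude))]
  expect_lt(abs(peak_hz - 350), 5 + sp$bin_width)
})

test_that("generate_cohort labels, counts and determinism", {
  spec_m <- quick_spec("M"); spec_c <- quick_spec("C")
  recs <- generate_cohort(spec_m, spec_c, 2, 3, seed = 9)
  expect_length(recs, 5)
  expect_equal(vapply(recs, function(r) r$metadata$group, ""),
               c("M", "M", "C", "C", "C"))
  recs2 <- generate_cohort(spec_m, spec_c, 2, 3, seed = 9)
  for (i in seq_along(recs)) {
    expect_identical(recs[[i]]$waveform$samples, recs2[[i]]$waveform$samples)
    expect_identical(recs[[i]]$metadata, recs2[[i]]$metadata)
    expect_identical(recs[[i]]$script$words, recs2[[i]]$script$words)
  }
  # metadata satisfies its group's inclusion criteria
  for (r in recs) expect_true(inclusion_filter(r$metadata)$include)
})

test_that("no rendered sample exceeds full scale", {
  set.seed(404)
  for (i in 1:10) {
    spec <- random_compatible_spec()
    sc <- plan_cry(spec, i)
    w <- render_cry(sc, spec)
    expect_lte(max(abs(w$samples)), 1)
  }
})

test_that("ground-truth sidecar round-trips through text", {
  sc <- plan_cry(quick_spec(), 21)
  path <- withr::local_tempfile(fileext = ".txt")
  write_cry_script(sc, path)
  back <- read_cry_script(path)
  expect_equal(back$total_duration, sc$total_duration, tolerance = 1e-6)
  for (col in c("phrase", "sentence", "word"))
    expect_identical(back$words[[col]], sc$words[[col]])
  for (col in c("onset", "duration", "f0"))
    expect_equal(back$words[[col]], sc$words[[col]], tolerance = 1e-4)
})
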