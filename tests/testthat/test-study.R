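test_that("metadata validation and inclusion criteria", {
  meta <- function(group, ga, apgar) {
    recording_metadata("NB X", 1, paste0(group, "1"), "F", "2010-01-01",
                       "08:00", 3400, 35, 33, 51, ga, apgar, "natural",
                       "cephalic", 1, 1, "", group)
  }
  expect_true(inclusion_filter(meta("M", 39, 10))$include)
  r <- inclusion_filter(meta("M", 39, 9))
  expect_false(r$include); expect_equal(r$reason, "Apgar")
  r2 <- inclusion_filter(meta("C", 37, 8))
  expect_false(r2$include); expect_equal(r2$reason, "GA")
  expect_true(inclusion_filter(meta("C", 38, 7))$include)
  r3 <- inclusion_filter(meta("M", 43, 10))
  expect_false(r3$include); expect_equal(r3$reason, "GA")

  expect_error(meta("X", 39, 10), "group")
  expect_error(meta("M", 39, 11), "apgar")
  expect_error(recording_metadata("x", 1, "Q1", "F", "d", "t", 3000, 35, 33,
                                  51, 39, 10, "natural", "cephalic", 1, 1,
                                  "", "M"), "indicative")
})

test_that("quality filter keeps clean cries and rejects noise", {
  spec <- quick_spec("M", noise_rms = 0.001)
  sc <- plan_cry(spec, 3)
  clean <- render_cry(sc, spec)
  q <- quality_filter(clean)
  expect_true(q$include)
  expect_gt(q$snr_db, 10)

  # quiet pure noise with an absolute threshold: nothing voiced at all
  set.seed(1)
  noise <- waveform(stats::rnorm(22050 * 3, 0, 0.0005), 22050)
  qn <- quality_filter(noise, cfg = segmentation_config(activity_threshold = 50))
  expect_false(qn$include)
  expect_equal(qn$reason, "no voiced frames")

  # loud broadband noise swamping the pauses: rejected on SNR
  noisy_spec <- quick_spec("M", noise_rms = 0.3)
  noisy <- render_cry(plan_cry(noisy_spec, 3), noisy_spec)
  expect_false(quality_filter(noisy)$include)
})

test_that("inclusion is monotone non-increasing as noise grows", {
  spec0 <- quick_spec("M")
  sc <- plan_cry(spec0, 6)
  includes <- vapply(c(0.001, 0.01, 0.1, 0.3), function(nr) {
    spec <- quick_spec("M", noise_rms = nr)
    quality_filter(render_cry(sc, spec, rng_seed = 10))$include
  }, logical(1))
  expect_true(all(diff(includes) <= 0))
  expect_true(includes[1])
  expect_false(includes[length(includes)])
})

test_that("wav files round-trip 16-bit samples exactly", {
  spec <- quick_spec("M", total_duration_range = c(2, 3))
  w <- render_cry(plan_cry(spec, 2), spec)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, w$sample_rate)
  expect_equal(length(back$samples), length(w$samples))
  # quantization error bounded by one PCM step
  expect_lt(max(abs(back$samples - w$samples)), 1 / 32767)
  # meters computed from the reloaded file match exactly (U is PCM-defined)
  expect_identical(compute_vu(back)$values, compute_vu(w)$values)
  expect_identical(compute_ppm(back)$values, compute_ppm(w)$values)
})

test_that("measurement bundles round-trip through their folder format", {
  spec <- quick_spec("M", total_duration_range = c(2, 3))
  w <- render_cry(plan_cry(spec, 4), spec)
  dir <- withr::local_tempdir()
  write_neonat_bundle(dir, "M1", w)
  files <- list.files(file.path(dir, "M1"))
  expect_setequal(files, c("M1.wav", "VU.txt", "PPM.txt", "Spectrum.txt"))
  back <- read_neonat_bundle(file.path(dir, "M1"))
  expect_equal(back$vu$values, compute_vu(w)$values, tolerance = 1e-6)
  expect_equal(back$ppm$values, compute_ppm(w)$values, tolerance = 1e-6)
  expect_equal(back$vu$frame_ms, 100)
  expect_equal(dim(back$spectrum$magnitude),
               dim(compute_spectrum(w)$magnitude))
})

small_cfg <- function(out_dir, n_m = 2, n_c = 2, ...) {
  study_config(
    spec_m = quick_spec("M", total_duration_range = c(5, 7)),
    spec_c = quick_spec("C", total_duration_range = c(5, 7)),
    n_m = n_m, n_c = n_c, out_dir = out_dir, seed = 33,
    classifiers = c("RT", "IB1"),
    protocols = c("training", "split75"),
    ...)
}

test_that("run_study writes the full report bundle with expected counts", {
  out <- withr::local_tempdir()
  res <- run_study(small_cfg(out))
  expect_equal(res$counts$M$included, 2)
  expect_equal(res$counts$C$included, 2)
  expect_length(list.dirs(file.path(out, "recordings"),
                          recursive = FALSE), 4)
  expect_true(all(file.exists(file.path(
    out, c("features_vu.arff", "features_ppm.arff", "metadata.tsv",
           "structure_summaries.tsv", "intensity_table.tsv",
           "study_log.txt")))))
  # one report per meter x classifier, each holding every protocol
  expect_length(list.files(out, pattern = "^classify_"), 4)
  expect_length(res$evaluations, 4)
  expect_named(res$evaluations$VU_RT, c("training", "split75"))
  # ARFF holds all four recordings
  d <- read_arff(file.path(out, "features_vu.arff"))
  expect_equal(nrow(d$x), 4)
  expect_equal(ncol(d$x), 300)
})

test_that("run_study is byte-identical when rerun with the same seed", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_study(small_cfg(out1))
  run_study(small_cfg(out2))
  f1 <- list.files(out1, recursive = TRUE)
  f2 <- list.files(out2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(out1, f1)))
  h2 <- unname(tools::md5sum(file.path(out2, f2)))
  expect_identical(h1, h2)
})

test_that("filter accounting: generated = included + excluded per group", {
  out <- withr::local_tempdir()
  res <- run_study(small_cfg(out, n_m = 4, n_c = 4, noisy_fraction = 0.5,
                             noisy_rms = 0.3))
  for (g in c("M", "C")) {
    cnt <- res$counts[[g]]
    expect_equal(cnt$generated, 4)
    expect_equal(cnt$included + cnt$excluded, cnt$generated)
    expect_equal(cnt$excluded, 2)   # the injected noisy recordings
  }
})

test_that("t-test on the preset study flags the VU minimum difference", {
  out <- withr::local_tempdir()
  res <- run_study(small_cfg(out, n_m = 8, n_c = 8))
  tt <- attr(res$intensity, "t_tests")
  expect_named(tt, c("VU", "PPM"))
  # direction: nuchal-cord group minima exceed control minima
  expect_gt(tt$VU$mean_b, tt$VU$mean_a)
})
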