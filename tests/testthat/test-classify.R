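fake_meter_record <- function(values, group) {
  list(group = group,
       vu = structure(list(values = values, kind = "VU", frame_ms = 100),
                      class = "meter_trace"),
       ppm = structure(list(values = values, kind = "PPM", frame_ms = 100),
                       class = "meter_trace"))
}

test_that("feature vectors truncate, pad and label correctly", {
  long_rec <- fake_meter_record(seq_len(900), "M")     # 90 s
  short_rec <- fake_meter_record(seq_len(100), "C")    # 10 s
  d <- build_feature_vectors(list(long_rec, short_rec), "VU")
  expect_equal(dim(d$x), c(2, 300))
  expect_equal(d$x[1, ], as.numeric(seq_len(300)), ignore_attr = TRUE)
  expect_equal(d$x[2, 1:100], as.numeric(seq_len(100)), ignore_attr = TRUE)
  expect_true(all(d$x[2, 101:300] == 0))
  expect_equal(as.character(d$class), c("M", "C"))
  expect_error(build_feature_vectors(list(), "VU"), "empty")
})

test_that("ARFF writer emits 301 attribute declarations and round-trips", {
  recs <- c(lapply(1:3, function(i)
    fake_meter_record(stats::runif(300, 0, 3000), "M")),
    lapply(1:2, function(i)
      fake_meter_record(stats::runif(250, 0, 3000), "C")))
  d <- build_feature_vectors(recs, "PPM")
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(d, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^@attribute", lines)), 301)
  back <- read_arff(path)
  expect_identical(back$x, d$x)
  expect_identical(back$class, d$class)
  expect_identical(back$meter, "PPM")
})

test_that("ARFF: empty dataset, parse errors with line numbers, interop", {
  d0 <- feature_dataset(matrix(numeric(0), 0, 5), factor(character(0),
                                                         levels = c("M", "C")))
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(d0, path)
  back <- read_arff(path)
  expect_equal(nrow(back$x), 0)
  expect_equal(ncol(back$x), 5)

  bad <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation x", "@attribute a1 numeric",
               "@attribute class {M,C}", "@data", "1.0,M", "oops,M"), bad)
  expect_error(read_arff(bad), "line 6")

  bad2 <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation x", "@attribute a1 numeric",
               "@attribute class {M,C}", "@data", "1.0,2.0,M"), bad2)
  expect_error(read_arff(bad2), "line 5")

  skip_if_not_installed("foreign")
  d <- blob_dataset(4, p = 6)
  path2 <- withr::local_tempfile(fileext = ".arff")
  write_arff(d, path2)
  ext <- foreign::read.arff(path2)
  expect_equal(as.matrix(ext[, 1:6]), d$x, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(as.character(ext$class), as.character(d$class))
})

test_that("training rejects degenerate datasets", {
  d <- blob_dataset(5)
  single <- feature_dataset(d$x[1:5, ], factor(rep("M", 5),
                                               levels = c("M", "C")))
  for (kind in c("RT", "DT", "IB1", "NNGE"))
    expect_error(train_classifier(kind, single), "single-class")
  one <- feature_dataset(d$x[1, , drop = FALSE], d$class[1])
  expect_error(train_classifier("IB1", one), ">= 2")
})

test_that("two separated instances are learned by every family", {
  d <- feature_dataset(rbind(c(0, 0), c(10, 10)),
                       factor(c("M", "C"), levels = c("M", "C")))
  for (kind in c("RT", "DT", "IB1", "NNGE")) {
    model <- train_classifier(kind, d, seed = 4)
    pred <- predict_cry(model, d$x)
    expect_equal(as.character(pred$class), c("M", "C"),
                 info = kind)
  }
})

test_that("IB1 matches the brute-force nearest-neighbour oracle", {
  set.seed(17)
  d <- blob_dataset(25, p = 8, sep = 1.5)   # overlapping blobs, n = 50
  model <- train_classifier("IB1", d)
  queries <- matrix(stats::rnorm(30 * 8, mean = 0.7), ncol = 8)
  pred <- predict_cry(model, queries)
  oracle <- apply(queries, 1, function(z) {
    dists <- apply(d$x, 1, function(t) sqrt(sum((t - z)^2)))
    as.character(d$class[which.min(dists)])
  })
  expect_equal(as.character(pred$class), oracle)
})

test_that("memorizing classifiers reach 100% on their own training data", {
  d <- blob_dataset(10, p = 10, sep = 6, seed = 2)
  for (kind in c("IB1", "RT", "NNGE")) {
    rep <- evaluate_classifier(kind, d, "training", seed = 3)
    expect_equal(rep$correctly_classified_pct, 100, info = kind)
    expect_equal(rep$incorrectly_classified_pct, 0, info = kind)
  }
  # perfect probabilistic predictions zero out the error indicators
  rep <- evaluate_classifier("IB1", d, "training", seed = 3)
  expect_equal(rep$mean_absolute_error, 0)
  expect_equal(rep$root_mean_squared_error, 0)
})

test_that("a prior-probability baseline scores RAE = RRSE = 100%", {
  d <- blob_dataset(6, p = 4)
  n <- nrow(d$x)
  B <- cryspect:::prior_matrix(d$class, n, levels(d$class))
  q <- cryspect:::quality_indicators(B, d$class, B, levels(d$class))
  expect_equal(q$relative_absolute_error_pct, 100)
  expect_equal(q$root_relative_squared_error_pct, 100)
})

test_that("stratified cv10 folds cover all instances with balanced classes", {
  d <- blob_dataset(26, p = 3, seed = 5)   # 52 instances
  fold <- stratified_folds(d$class, 10, seed = 6)
  expect_equal(length(fold), 52)
  expect_equal(sort(unique(fold)), 1:10)
  global_ratio <- mean(d$class == "M")
  for (f in 1:10) {
    in_fold <- d$class[fold == f]
    expect_lte(abs(sum(in_fold == "M") - global_ratio * length(in_fold)), 1)
  }
})

test_that("confusion matrices conserve instance counts in every protocol", {
  d <- blob_dataset(12, p = 6, sep = 2, seed = 7)
  for (protocol in c("training", "cv10", "split75")) {
    rep <- evaluate_classifier("IB1", d, protocol, seed = 11)
    expect_equal(sum(rep$confusion_matrix), rep$n_evaluated)
    expect_equal(rowSums(rep$confusion_matrix),
                 as.numeric(table(d$class))[
                   if (protocol == "split75") c(1, 2) else c(1, 2)] *
                   (if (protocol == "split75") 0.25 else 1),
                 ignore_attr = TRUE)
  }
})

test_that("evaluation is deterministic under a fixed seed", {
  d <- blob_dataset(12, p = 6, sep = 1, seed = 9)
  for (kind in c("RT", "IB1")) {
    r1 <- evaluate_classifier(kind, d, "cv10", seed = 21)
    r2 <- evaluate_classifier(kind, d, "cv10", seed = 21)
    expect_identical(r1, r2)
  }
})

test_that("IB1 cross-validates above 90% on well-separated cohorts", {
  # separation constructed: the groups differ strongly in intensity scale
  spec_m <- cry_preset("M", amplitude_mean = 2500, amplitude_min_mean = 1000,
                       total_duration_range = c(8, 12), noise_rms = 0)
  spec_c <- cry_preset("C", amplitude_mean = 15000, amplitude_min_mean = 6000,
                       total_duration_range = c(8, 12), noise_rms = 0)
  recs <- generate_cohort(spec_m, spec_c, 8, 8, seed = 15,
                          callback = function(rec, i)
                            list(group = rec$metadata$group,
                                 vu = compute_vu(rec$waveform),
                                 ppm = compute_ppm(rec$waveform)))
  d <- build_feature_vectors(recs, "VU")
  rep <- evaluate_classifier("IB1", d, "cv10", seed = 2)
  expect_gte(rep$correctly_classified_pct, 90)
})
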