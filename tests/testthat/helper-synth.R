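# Shared fixtures: small, fast synthetic specs built in code.

# short recordings for unit tests; group presets otherwise untouched
quick_spec <- function(group = "M", ...) {
  args <- utils::modifyList(list(total_duration_range = c(6, 10),
                                 noise_rms = 0), list(...))
  do.call(cry_preset, c(list(group = group), args))
}

# a degenerate spec producing exactly one phrase of 2 sentences x 3 words
fixed_structure_spec <- function(...) {
  args <- list(words_per_sentence_range = c(3, 3),
               words_per_sentence_mean = 3, words_per_sentence_sd = 0,
               sentences_per_phrase_range = c(2, 2),
               word_duration_mean = 0.5, word_duration_range = c(0.5, 0.5),
               first_word_duration_mean = 0.5, first_word_duration_sd = 0,
               total_duration_range = c(6, 6), noise_rms = 0)
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

# synthesize a small cohort keeping only meter traces + labels (the shape
# expected by intensity_table and build_feature_vectors)
tiny_trace_records <- function(n_m, n_c, seed = 1,
                               dur = c(8, 12), spectrum = FALSE) {
  spec_m <- cry_preset("M", total_duration_range = dur, noise_rms = 0)
  spec_c <- cry_preset("C", total_duration_range = dur, noise_rms = 0)
  generate_cohort(spec_m, spec_c, n_m, n_c, seed, callback = function(rec, i) {
    out <- list(metadata = rec$metadata, group = rec$metadata$group,
                vu = compute_vu(rec$waveform),
                ppm = compute_ppm(rec$waveform),
                script = rec$script)
    if (spectrum) out$spectrum <- compute_spectrum(rec$waveform)
    out
  })
}

# a random generator spec guaranteed compatible with the default
# segmentation config (words >= min_word_ms, pauses straddle the gap
# thresholds, intensities above the adaptive activity floor)
random_compatible_spec <- function() {
  gap <- round(stats::runif(1, 0.2, 0.6), 1)
  spause <- round(stats::runif(1, 1.1, 2.5), 1)
  ppause <- round(stats::runif(1, 3.1, 5.0), 1)
  wmin <- round(stats::runif(1, 0.3, 0.6), 1)
  wmax <- wmin + round(stats::runif(1, 0.5, 2.0), 1)
  amp <- stats::runif(1, 4000, 12000)
  synth_spec(
    f0_mean = stats::runif(1, 250, 450),
    n_harmonics = sample(1:6, 1),
    words_per_sentence_mean = stats::runif(1, 3, 10),
    words_per_sentence_sd = stats::runif(1, 0.5, 3),
    words_per_sentence_range = c(2, 14),
    sentences_per_phrase_range = c(1, 3),
    word_duration_mean = mean(c(wmin, wmax)),
    word_duration_range = c(wmin, wmax),
    first_word_duration_mean = mean(c(wmin, wmax)),
    first_word_duration_sd = 0.2,
    intra_sentence_gap = gap,
    inter_sentence_pause = spause,
    inter_phrase_pause = ppause,
    amplitude_mean = amp,
    amplitude_min_mean = 0.4 * amp,
    amplitude_cv = 0.2,
    noise_rms = 0,
    total_duration_range = c(5, 15))
}

script_counts <- function(script) {
  w <- script$words
  list(words = nrow(w),
       sentences = nrow(unique(w[c("phrase", "sentence")])),
       phrases = length(unique(w$phrase)))
}

structure_counts <- function(s) {
  list(words = nrow(s),
       sentences = if (nrow(s)) nrow(unique(s[c("phrase", "sentence")])) else 0L,
       phrases = length(unique(s$phrase)))
}

# deterministic separable dataset for classifier unit tests: two gaussian
# blobs in p dimensions, duplicate-free
blob_dataset <- function(n_per_class = 10, p = 12, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = sep), ncol = p))
  feature_dataset(x, factor(rep(c("M", "C"), each = n_per_class),
                            levels = c("M", "C")))
}
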