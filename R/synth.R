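#' Specification of a synthetic cry recording
#'
#' Parameters of the synthetic cry generator. A cry is scripted as a hierarchy
#' of phrases (groups of cry bursts), sentences (cry bursts) and words (single
#' expiratory vocalizations), then rendered as harmonic-stack audio with an
#' attack-sustain-decay envelope per word and silence (plus optional Gaussian
#' noise) elsewhere.
#'
#' Intensity levels (`amplitude_mean`, `amplitude_min_mean`) are given in the
#' meter's U units and control the sustained VU level of a word;
#' `amplitude_min_mean` is the target level of each recording's quietest word,
#' so the distribution of per-recording minimum intensities is controlled
#' directly. Word onsets, durations and pauses are quantized to the 100 ms
#' meter grid so that meter-domain segmentation and script ground truth are
#' commensurate.
#'
#' @param sample_rate sampling rate, Hz.
#' @param f0_mean mean fundamental frequency, Hz (must lie in 150-800 Hz;
#'   healthy-newborn presets use the 250-450 Hz band).
#' @param f0_jitter relative SD of per-word F0 draws (>= 0).
#' @param n_harmonics number of harmonics in the source stack (>= 1), with
#'   1/k amplitude roll-off.
#' @param words_per_sentence_mean,words_per_sentence_sd,words_per_sentence_range
#'   parameters of the truncated discrete normal from which the number of
#'   words in each sentence is drawn (rounded, clipped to the range).
#' @param sentences_per_phrase_range integer range; sentences per phrase are
#'   drawn uniformly from it.
#' @param word_duration_mean mean word duration, s.
#' @param word_duration_range clip range for word durations, s (within
#'   0.1-5 s).
#' @param first_word_duration_mean mean duration of the recording's first
#'   word, s (drawn separately; the first expiration of a cry is typically
#'   longer than the rest).
#' @param first_word_duration_sd SD of the first-word duration draw, s.
#' @param intra_sentence_gap inhalation pause between words in a sentence, s.
#' @param inter_sentence_pause pause between sentences within a phrase, s.
#' @param inter_phrase_pause pause between phrases, s. The three pauses must
#'   be strictly increasing so segmentation is well-posed.
#' @param amplitude_mean mean sustained word VU level, U.
#' @param amplitude_min_mean mean (over recordings) of the quietest word's
#'   sustained VU level, U.
#' @param amplitude_cv coefficient of variation of the lognormal intensity
#'   draws (free dispersion parameter; the source tables print no SD).
#' @param noise_rms RMS of additive Gaussian background noise, normalized
#'   amplitude.
#' @param total_duration_range range of the recording duration, s.
#' @param seed integer seed stored with the spec.
#' @return An object of class `synth_spec`.
#' @seealso [cry_preset()], [plan_cry()], [render_cry()], [generate_cohort()]
#' @export
synth_spec <- function(sample_rate = 22050,
                       f0_mean = 350,
                       f0_jitter = 0.05,
                       n_harmonics = 5,
                       words_per_sentence_mean = 9.45,
                       words_per_sentence_sd = 3.381,
                       words_per_sentence_range = c(4, 18),
                       sentences_per_phrase_range = c(1, 3),
                       word_duration_mean = 1.0,
                       word_duration_range = c(0.5, 2.9),
                       first_word_duration_mean = 1.21,
                       first_word_duration_sd = 0.4,
                       intra_sentence_gap = 0.3,
                       inter_sentence_pause = 1.5,
                       inter_phrase_pause = 4.0,
                       amplitude_mean = 7300,
                       amplitude_min_mean = 2200,
                       amplitude_cv = 0.5,
                       noise_rms = 0.001,
                       total_duration_range = c(30, 90),
                       seed = 1L) {
  spec <- structure(as.list(environment()), class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  chk_range <- function(r, field) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop_invalid(field, "must be a finite [min, max] pair with min <= max")
  }
  if (spec$sample_rate <= 0 || spec$sample_rate != round(spec$sample_rate))
    stop_invalid("sample_rate", "must be a positive integer")
  if (spec$f0_mean < 150 || spec$f0_mean > 800)
    stop_invalid("f0_mean", "must lie within [150, 800] Hz")
  if (spec$f0_jitter < 0) stop_invalid("f0_jitter", "must be >= 0")
  if (spec$n_harmonics < 1) stop_invalid("n_harmonics", "must be >= 1")
  chk_range(spec$words_per_sentence_range, "words_per_sentence_range")
  if (spec$words_per_sentence_range[1] < 1)
    stop_invalid("words_per_sentence_range", "must be >= 1")
  chk_range(spec$sentences_per_phrase_range, "sentences_per_phrase_range")
  if (spec$sentences_per_phrase_range[1] < 1)
    stop_invalid("sentences_per_phrase_range", "must be >= 1")
  for (f in c("word_duration_mean", "first_word_duration_mean",
              "intra_sentence_gap", "inter_sentence_pause",
              "inter_phrase_pause")) {
    if (spec[[f]] <= 0) stop_invalid(f, "must be > 0")
  }
  chk_range(spec$word_duration_range, "word_duration_range")
  if (spec$word_duration_range[1] < 0.1 || spec$word_duration_range[2] > 5)
    stop_invalid("word_duration_range", "must lie within [0.1 s, 5 s]")
  if (!(spec$intra_sentence_gap < spec$inter_sentence_pause &&
        spec$inter_sentence_pause < spec$inter_phrase_pause))
    stop_invalid("pauses",
                 "must satisfy intra_sentence_gap < inter_sentence_pause < inter_phrase_pause")
  if (spec$amplitude_mean <= 0 || spec$amplitude_mean > U_FULL_SCALE)
    stop_invalid("amplitude_mean", "must be in (0, 32767] U")
  if (spec$amplitude_min_mean <= 0 ||
      spec$amplitude_min_mean > spec$amplitude_mean)
    stop_invalid("amplitude_min_mean", "must be in (0, amplitude_mean] U")
  if (spec$amplitude_cv < 0) stop_invalid("amplitude_cv", "must be >= 0")
  if (spec$noise_rms < 0) stop_invalid("noise_rms", "must be >= 0")
  chk_range(spec$total_duration_range, "total_duration_range")
  if (spec$total_duration_range[1] <= 0)
    stop_invalid("total_duration_range", "must be positive")
  invisible(spec)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec: f0 %g Hz, %g words/sentence (sd %g, range %g-%g), %g-%g s>\n",
    x$f0_mean, x$words_per_sentence_mean, x$words_per_sentence_sd,
    x$words_per_sentence_range[1], x$words_per_sentence_range[2],
    x$total_duration_range[1], x$total_duration_range[2]))
  invisible(x)
}

#' Study-group presets for the synthetic generator
#'
#' Returns the `synth_spec` emulating one of the two study cohorts. Group "M"
#' (control, eventless intrapartum) uses the control-group cry structure:
#' words per sentence with mean 9.45, SD 3.381, range 4-18. Group "C" (tight
#' nuchal cord) uses mean 7.65, SD 2.485, range 4-14, higher overall and
#' minimum intensity levels (the nuchal-cord cohort's distinguishing feature
#' is an elevated per-recording minimum intensity: its quietest cry frames are
#' louder than the control group's).
#'
#' The absolute U scale of the original meters is not recoverable, so preset
#' intensity levels preserve the printed between-group ordering and
#' approximate ratios while keeping the quietest words above the default
#' voice-activity floor; see the package vignette.
#'
#' @param group `"M"` (control) or `"C"` (nuchal cord).
#' @param ... overrides passed on to [synth_spec()].
#' @return A `synth_spec`.
#' @export
cry_preset <- function(group = c("M", "C"), ...) {
  group <- match.arg(group)
  args <- if (group == "M") {
    list(words_per_sentence_mean = 9.45, words_per_sentence_sd = 3.381,
         words_per_sentence_range = c(4, 18),
         amplitude_mean = 7300, amplitude_min_mean = 2200)
  } else {
    list(words_per_sentence_mean = 7.65, words_per_sentence_sd = 2.485,
         words_per_sentence_range = c(4, 14),
         amplitude_mean = 8770, amplitude_min_mean = 4800)
  }
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

# mean(|shape|) / max(|shape|) for the zero-phase 1/k harmonic stack; used to
# convert a target sustained VU level in U into a normalized peak amplitude.
stack_mean_peak_ratio <- function(n_harmonics) {
  t <- seq(0, 1, length.out = 8192 + 1)[-1]
  s <- rowSums(vapply(seq_len(n_harmonics),
                      function(k) sin(2 * pi * k * t) / k,
                      numeric(length(t))))
  mean(abs(s)) / max(abs(s))
}

u_level_to_peak <- function(level_u, ratio) {
  pmin(level_u / (U_FULL_SCALE * ratio), 1)
}

#' Plan a synthetic cry: sample its word/sentence/phrase script
#'
#' Draws the hierarchical structure of one cry recording: the total duration
#' (uniform in `total_duration_range`), sentences per phrase (uniform
#' integers), words per sentence (discrete normal, rounded and clipped to the
#' spec range), word durations (normal, clipped to the spec range; the
#' recording's first word has its own distribution), a per-word F0 and a
#' per-word intensity level. The recording's quietest word is forced to the
#' per-recording minimum-intensity level so group minima are controlled.
#'
#' All onsets and durations are quantized to the 100 ms meter grid. Trailing
#' structure that does not fit the drawn total duration is truncated at
#' sentence boundaries (a sentence is only emitted whole, so pooled
#' words-per-sentence statistics are unbiased); if even the first word does
#' not fit, a single word truncated to the total duration is emitted.
#'
#' @param spec a [synth_spec()].
#' @param rng_seed integer seed for this plan.
#' @return A `cry_script`: list with `words` (data.frame with 0-based
#'   `phrase`, `sentence`, `word` indices, `onset` and `duration` in seconds,
#'   `peak_amplitude` normalized, `level_u`, `f0` in Hz) and `total_duration`.
#' @export
plan_cry <- function(spec, rng_seed = spec$seed) {
  validate_synth_spec(spec)
  with_seed(rng_seed, plan_cry_impl(spec))
}

plan_cry_impl <- function(spec) {
  grid <- 0.1
  total <- snap_grid(stats::runif(1, spec$total_duration_range[1],
                                  spec$total_duration_range[2]), grid)
  wr <- spec$word_duration_range
  word_sd <- diff(wr) / 4

  ratio <- stack_mean_peak_ratio(spec$n_harmonics)
  # cap word levels so the loudest word still renders below full scale
  cap_u <- min(2.2 * spec$amplitude_mean, 0.95 * U_FULL_SCALE * ratio)
  min_u <- rlnorm_mean_cv(1, spec$amplitude_min_mean, spec$amplitude_cv)
  # keep the quietest word above the relative voice-activity floor
  min_u <- min(max(min_u, 0.08 * cap_u), spec$amplitude_mean)

  draw_words <- function(n, first = FALSE) {
    d <- rnorm_clipped(n, spec$word_duration_mean, word_sd, wr)
    if (first)
      d[1] <- rnorm_clipped(1, spec$first_word_duration_mean,
                            spec$first_word_duration_sd, wr)
    pmax(snap_grid(d, grid), 2 * grid)
  }

  rows <- list()
  cursor <- 0
  phrase <- 0L
  sentence <- 0L
  done <- FALSE
  sample_int_range <- function(r) {
    if (r[1] == r[2]) return(as.integer(r[1]))
    sample(seq(as.integer(r[1]), as.integer(r[2])), 1)
  }
  while (!done) {
    n_sent <- sample_int_range(spec$sentences_per_phrase_range)
    for (s in seq_len(n_sent)) {
      n_words <- as.integer(round(stats::rnorm(1,
                                               spec$words_per_sentence_mean,
                                               spec$words_per_sentence_sd)))
      n_words <- min(max(n_words, spec$words_per_sentence_range[1]),
                     spec$words_per_sentence_range[2])
      durs <- draw_words(n_words, first = length(rows) == 0)
      span <- sum(durs) + (n_words - 1) * spec$intra_sentence_gap
      start <- if (sentence == 0L) 0 else cursor
      if (start + span > total + 1e-9) {
        if (length(rows) == 0) {
          # degenerate budget: emit words while they fit, truncating the first
          onset <- 0
          for (i in seq_len(n_words)) {
            d <- min(durs[i], total - onset)
            d <- snap_grid(d, grid)
            # a truncated continuation word must still be a detectable word;
            # only the very first word may shrink to a single frame
            if (d < grid - 1e-9 || (i > 1 && d < 2 * grid - 1e-9)) break
            rows[[length(rows) + 1]] <-
              data.frame(phrase = 0L, sentence = 0L, word = i - 1L,
                         onset = onset, duration = d)
            onset <- onset + d + spec$intra_sentence_gap
            if (onset >= total - 1e-9) break
          }
          sentence <- 1L
          phrase <- 1L
        }
        done <- TRUE
        break
      }
      onsets <- start + cumsum(c(0, durs[-n_words] + spec$intra_sentence_gap))
      rows[[length(rows) + 1]] <-
        data.frame(phrase = phrase, sentence = sentence,
                   word = seq_len(n_words) - 1L,
                   onset = onsets, duration = durs)
      cursor <- onsets[n_words] + durs[n_words] +
        if (s < n_sent) spec$inter_sentence_pause else spec$inter_phrase_pause
      sentence <- sentence + 1L
    }
    if (!done) phrase <- phrase + 1L
  }

  words <- do.call(rbind, rows)
  words <- words[order(words$onset), , drop = FALSE]
  rownames(words) <- NULL
  # renumber sentences within phrases to 0-based contiguous pairs
  sent_global <- words$sentence
  words$sentence <- stats::ave(sent_global, words$phrase,
                               FUN = function(s) match(s, unique(s)) - 1L)
  words$sentence <- as.integer(words$sentence)

  n <- nrow(words)
  level <- rlnorm_mean_cv(n, spec$amplitude_mean, spec$amplitude_cv)
  level <- pmin(pmax(level, min_u), cap_u)
  level[which.min(level)] <- min_u
  words$level_u <- level
  words$peak_amplitude <- u_level_to_peak(level, ratio)
  f0 <- stats::rnorm(n, spec$f0_mean, spec$f0_jitter * spec$f0_mean)
  words$f0 <- pmin(pmax(f0, 150), 800)

  structure(list(words = words, total_duration = total),
            class = "cry_script")
}

#' @export
print.cry_script <- function(x, ...) {
  w <- x$words
  cat(sprintf(
    "<cry_script: %d words, %d sentences, %d phrases, %.1f s>\n",
    nrow(w), nrow(unique(w[c("phrase", "sentence")])),
    length(unique(w$phrase)), x$total_duration))
  invisible(x)
}

#' Render a cry script as audio
#'
#' Each word is rendered as a zero-phase harmonic stack at its F0
#' (`n_harmonics` partials with 1/k roll-off, normalized to unit peak) under a
#' linear attack (15 ms) - sustain - decay (30 ms) envelope scaled to the
#' word's peak amplitude. Everywhere else is silence; Gaussian noise at
#' `noise_rms` is added over the whole signal. The output is clipped to
#' `[-1, 1]`.
#'
#' @param script a `cry_script` from [plan_cry()].
#' @param spec the [synth_spec()] the script was planned from.
#' @param rng_seed seed for the background-noise draw.
#' @return A [waveform] of length `round(total_duration * sample_rate)`.
#' @export
render_cry <- function(script, spec, rng_seed = spec$seed + 1) {
  stopifnot(inherits(script, "cry_script"))
  validate_synth_spec(spec)
  sr <- spec$sample_rate
  n <- round(script$total_duration * sr)
  y <- numeric(n)
  w <- script$words
  if (nrow(w) > 0 && max(w$onset + w$duration) > script$total_duration + 1e-6)
    stop("script words exceed total_duration", call. = FALSE)
  nyq <- sr / 2
  for (i in seq_len(nrow(w))) {
    len <- round(w$duration[i] * sr)
    if (len < 1) next
    i0 <- round(w$onset[i] * sr)
    t <- (seq_len(len) - 1) / sr
    ks <- seq_len(spec$n_harmonics)
    ks <- ks[ks * w$f0[i] < nyq]
    shape <- rowSums(vapply(ks, function(k) sin(2 * pi * k * w$f0[i] * t) / k,
                            numeric(len)))
    shape <- shape / max(abs(shape))
    env <- word_envelope(len, sr)
    idx <- (i0 + 1):(i0 + len)
    y[idx] <- w$peak_amplitude[i] * shape * env
  }
  if (spec$noise_rms > 0)
    y <- y + with_seed(rng_seed, stats::rnorm(n, 0, spec$noise_rms))
  waveform(pmin(pmax(y, -1), 1), sr)
}

# linear attack/sustain/decay envelope; attack and decay are shortened on
# very short words so they never overlap
word_envelope <- function(len, sr, attack_s = 0.015, decay_s = 0.03) {
  na <- min(round(attack_s * sr), len %/% 3)
  nd <- min(round(decay_s * sr), len %/% 3)
  env <- rep(1, len)
  if (na > 0) env[seq_len(na)] <- seq_len(na) / na
  if (nd > 0) env[(len - nd + 1):len] <- rev(seq_len(nd)) / nd
  env
}

#' Synthesize one cohort recording (plan, render, metadata)
#'
#' @param spec a [synth_spec()].
#' @param group group label, `"M"` or `"C"`.
#' @param id 1-based recording ordinal within its group.
#' @param seed master seed; the recording's plan, render-noise and metadata
#'   seeds are derived from it deterministically.
#' @return List with elements `waveform`, `metadata`
#'   ([recording_metadata()]) and `script` (`cry_script`).
#' @export
synth_recording <- function(spec, group, id, seed) {
  offset <- if (group == "M") 0L else 100000L
  s_plan <- derive_seed(seed, offset + 3L * id)
  s_noise <- derive_seed(seed, offset + 3L * id + 1L)
  s_meta <- derive_seed(seed, offset + 3L * id + 2L)
  script <- plan_cry(spec, s_plan)
  wav <- render_cry(script, spec, s_noise)
  meta <- with_seed(s_meta, synth_metadata(group, id))
  list(waveform = wav, metadata = meta, script = script)
}

# random clinical metadata satisfying the group's inclusion criteria
synth_metadata <- function(group, id) {
  ga <- sample(38:42, 1)
  apgar <- if (group == "M") 10L else sample(7:10, 1)
  recording_metadata(
    first_last_name = sprintf("NB %s%d", group, id),
    number = id,
    indicative = sprintf("%s%d", group, id),
    sex = sample(c("M", "F"), 1),
    date_of_birth = sprintf("2010-%02d-%02d", sample(1:12, 1), sample(1:28, 1)),
    time_of_birth = sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)),
    weight_g = round(stats::runif(1, 2800, 4200)),
    head_circumference_cm = round(stats::runif(1, 33, 37), 1),
    chest_circumference_cm = round(stats::runif(1, 31, 35), 1),
    length_cm = round(stats::runif(1, 48, 55), 1),
    gestational_age_weeks = ga,
    apgar = apgar,
    birth_type = sample(c("natural", "caesarian"), 1),
    presentation = sample(c("cephalic", "pelvic", "transverse"), 1,
                          prob = c(0.9, 0.08, 0.02)),
    gesta = sample(1:4, 1),
    para = sample(1:2, 1),
    other_info = "",
    group = group
  )
}

#' Generate a two-group synthetic cohort
#'
#' Generates `n_m` recordings under the group-M spec followed by `n_c` under
#' the group-C spec. Per-recording seeds are derived deterministically from
#' the master seed, so the whole cohort is reproducible bit-for-bit.
#'
#' @param spec_m,spec_c [synth_spec()] for each group.
#' @param n_m,n_c number of recordings per group (>= 1).
#' @param seed master integer seed.
#' @param keep_audio if `FALSE`, drop each record's waveform after synthesis
#'   (the returned record keeps metadata and script only); use the callback
#'   for streaming processing of large cohorts.
#' @param callback optional `function(record, index)` called with each record
#'   as it is generated; its return value, when not `NULL`, replaces the
#'   record in the result (useful to retain only derived traces).
#' @return List of records as returned by [synth_recording()] (or by
#'   `callback`), groups M then C.
#' @export
generate_cohort <- function(spec_m, spec_c, n_m, n_c, seed,
                            keep_audio = TRUE, callback = NULL) {
  stopifnot(n_m >= 1, n_c >= 1)
  out <- vector("list", n_m + n_c)
  plan <- rbind(data.frame(group = rep("M", n_m), id = seq_len(n_m)),
                data.frame(group = rep("C", n_c), id = seq_len(n_c)))
  for (i in seq_len(nrow(plan))) {
    spec <- if (plan$group[i] == "M") spec_m else spec_c
    rec <- synth_recording(spec, plan$group[i], plan$id[i], seed)
    if (!keep_audio) rec$waveform <- NULL
    if (!is.null(callback)) {
      r <- callback(rec, i)
      if (!is.null(r)) rec <- r
    }
    out[[i]] <- rec
  }
  out
}

#' Draw per-recording minimum-intensity levels
#'
#' Samples per-recording minimum meter values (the quietest cry-active frame
#' of each recording) from a lognormal distribution parameterized by its
#' arithmetic mean and coefficient of variation. This is the statistical
#' model used to replicate the group comparison of per-recording minima at
#' the printed group mean-minimum levels.
#'
#' @param n number of recordings.
#' @param mean_u group mean of per-recording minima, U.
#' @param cv coefficient of variation (default 0.5).
#' @return Numeric vector of length `n`, in U.
#' @export
sample_min_intensity <- function(n, mean_u, cv = 0.5) {
  rlnorm_mean_cv(n, mean_u, cv)
}

#' Write / read the ground-truth sidecar of a cry script
#'
#' Tab-separated text, one word per line: 0-based phrase, sentence and word
#' indices, onset (s), duration (s), peak amplitude (normalized) and F0 (Hz),
#' preceded by a comment header carrying the total duration.
#'
#' @param script a `cry_script`.
#' @param path file path.
#' @return `write_cry_script()`: `path` invisibly; `read_cry_script()`: a
#'   `cry_script`.
#' @export
write_cry_script <- function(script, path) {
  stopifnot(inherits(script, "cry_script"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cry_script\ttotal_duration\t%.6f",
                     script$total_duration), con)
  writeLines("phrase\tsentence\tword\tonset_s\tduration_s\tpeak_amplitude\tf0_hz",
             con)
  w <- script$words
  writeLines(sprintf("%d\t%d\t%d\t%.6f\t%.6f\t%.8f\t%.4f",
                     w$phrase, w$sentence, w$word, w$onset, w$duration,
                     w$peak_amplitude, w$f0), con)
  invisible(path)
}

#' @rdname write_cry_script
#' @export
read_cry_script <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  total <- as.numeric(hdr[3])
  df <- utils::read.delim(text = lines[-1])
  words <- data.frame(phrase = as.integer(df$phrase),
                      sentence = as.integer(df$sentence),
                      word = as.integer(df$word),
                      onset = df$onset_s, duration = df$duration_s,
                      level_u = NA_real_,
                      peak_amplitude = df$peak_amplitude, f0 = df$f0_hz)
  structure(list(words = words, total_duration = total), class = "cry_script")
}
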