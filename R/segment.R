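#' Segmentation configuration
#'
#' Parameters of the silence-based cry-to-language segmentation. A *word* is
#' a maximal run of 100 ms VU frames above the activity threshold (an
#' expiratory vocalization); words separated by a silence no longer than
#' `sentence_gap_ms` (inhalation gaps) share a *sentence* (cry burst);
#' sentences separated by a silence no longer than `phrase_gap_ms` share a
#' *phrase*.
#'
#' @param activity_threshold voice-activity threshold in U, or `NULL` (the
#'   default) for the adaptive rule `max(50 U, 5%` of the trace maximum`)`
#'   applied per trace by [default_activity_threshold()].
#' @param min_word_ms minimum word duration, ms; shorter active runs are
#'   discarded as clicks.
#' @param sentence_gap_ms a silence longer than this (ms) ends a sentence.
#' @param phrase_gap_ms a silence longer than this (ms) ends a phrase; must
#'   exceed `sentence_gap_ms`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(activity_threshold = NULL,
                                min_word_ms = 200,
                                sentence_gap_ms = 1000,
                                phrase_gap_ms = 3000) {
  if (!is.null(activity_threshold) && activity_threshold < 0)
    stop_invalid("activity_threshold", "must be >= 0")
  if (min_word_ms <= 0) stop_invalid("min_word_ms", "must be > 0")
  if (!(sentence_gap_ms > 0 && sentence_gap_ms < phrase_gap_ms))
    stop_invalid("gaps", "need 0 < sentence_gap_ms < phrase_gap_ms")
  structure(list(activity_threshold = activity_threshold,
                 min_word_ms = min_word_ms,
                 sentence_gap_ms = sentence_gap_ms,
                 phrase_gap_ms = phrase_gap_ms),
            class = "segmentation_config")
}

#' Detect words (expiratory vocalizations) in a VU trace
#'
#' Words are maximal runs of consecutive frames with VU value strictly above
#' the activity threshold; runs shorter than `min_word_ms` are discarded.
#' Onsets and durations are reported in seconds on the frame grid, as
#' half-open intervals `[onset, onset + duration)`.
#'
#' @param vu a VU `meter_trace` (see [compute_vu()]).
#' @param cfg a [segmentation_config()].
#' @return data.frame with columns `onset`, `duration` (seconds); zero rows
#'   when nothing is active.
#' @export
detect_words <- function(vu, cfg = segmentation_config()) {
  stopifnot(inherits(vu, "meter_trace"))
  if (vu$kind != "VU") stop("detect_words needs a VU trace", call. = FALSE)
  stopifnot(inherits(cfg, "segmentation_config"))
  frame_s <- vu$frame_ms / 1000
  empty <- data.frame(onset = numeric(0), duration = numeric(0))
  if (!length(vu$values)) return(empty)
  thr <- cfg$activity_threshold %||% default_activity_threshold(vu)
  active <- vu$values > thr
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * vu$frame_ms >= cfg$min_word_ms
  data.frame(onset = (starts[keep] - 1) * frame_s,
             duration = r$lengths[keep] * frame_s)
}

#' Group detected words into sentences and phrases
#'
#' Consecutive words separated by a silence `<= sentence_gap_ms` share a
#' sentence; consecutive sentences separated by a silence `<= phrase_gap_ms`
#' share a phrase; any longer silence starts a new unit.
#'
#' @param words data.frame with `onset`, `duration` (seconds), time-ordered
#'   (as returned by [detect_words()]).
#' @param cfg a [segmentation_config()].
#' @return A `cry_structure`: data.frame with 0-based `phrase`, `sentence`
#'   (within phrase), `word` (within sentence) indices plus `onset`,
#'   `duration`; the config is attached as attribute `config`.
#' @export
group_structure <- function(words, cfg = segmentation_config()) {
  stopifnot(is.data.frame(words))
  n <- nrow(words)
  if (n > 1 && any(diff(words$onset) < 0))
    stop("words must be time-ordered", call. = FALSE)
  if (n == 0) {
    out <- data.frame(phrase = integer(0), sentence = integer(0),
                      word = integer(0), onset = numeric(0),
                      duration = numeric(0))
    return(structure(out, class = c("cry_structure", "data.frame"),
                     config = cfg))
  }
  gap <- c(Inf, words$onset[-1] - (words$onset[-n] + words$duration[-n]))
  new_sentence <- gap > cfg$sentence_gap_ms / 1000
  new_phrase <- gap > cfg$phrase_gap_ms / 1000
  sentence_global <- cumsum(new_sentence) - 1L
  phrase <- cumsum(new_phrase) - 1L
  sentence <- stats::ave(sentence_global, phrase,
                         FUN = function(s) match(s, unique(s)) - 1L)
  word <- stats::ave(seq_len(n), sentence_global,
                     FUN = function(i) seq_along(i) - 1L)
  out <- data.frame(phrase = as.integer(phrase),
                    sentence = as.integer(sentence),
                    word = as.integer(word),
                    onset = words$onset, duration = words$duration)
  structure(out, class = c("cry_structure", "data.frame"), config = cfg)
}

#' Segment a waveform end-to-end
#'
#' Convenience wrapper: VU trace, word detection, grouping.
#'
#' @param w a [waveform] or a VU `meter_trace`.
#' @param cfg a [segmentation_config()].
#' @param frame_ms meter frame length, ms.
#' @return A `cry_structure` (see [group_structure()]).
#' @export
segment_cry <- function(w, cfg = segmentation_config(), frame_ms = 100) {
  vu <- if (inherits(w, "meter_trace")) w else compute_vu(w, frame_ms)
  group_structure(detect_words(vu, cfg), cfg)
}

#' @export
print.cry_structure <- function(x, ...) {
  cat(sprintf("<cry_structure: %d words, %d sentences, %d phrases>\n",
              nrow(x),
              if (nrow(x)) nrow(unique(x[c("phrase", "sentence")])) else 0L,
              length(unique(x$phrase))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Per-recording structural statistics of a segmented cry
#'
#' Sentence durations (last word end minus first word onset within each
#' sentence), words-per-sentence counts, the duration of the recording's
#' first word, phrase count, and total cry (voiced) time.
#'
#' @param s a `cry_structure` from [group_structure()].
#' @return List with `sentence_durations` (s), `words_per_sentence` (integer
#'   vector), `first_word_duration` (s, `NA` when the structure is empty),
#'   `n_words`, `n_sentences`, `n_phrases`, `total_cry_time` (s).
#' @export
structure_stats <- function(s) {
  stopifnot(inherits(s, "cry_structure"))
  if (nrow(s) == 0) {
    return(list(sentence_durations = numeric(0),
                words_per_sentence = integer(0),
                first_word_duration = NA_real_,
                n_words = 0L, n_sentences = 0L, n_phrases = 0L,
                total_cry_time = 0))
  }
  key <- paste(s$phrase, s$sentence, sep = ".")
  key <- factor(key, levels = unique(key))
  ends <- s$onset + s$duration
  sent_dur <- as.numeric(tapply(ends, key, max) - tapply(s$onset, key, min))
  wps <- as.integer(tapply(s$onset, key, length))
  list(sentence_durations = sent_dur,
       words_per_sentence = wps,
       first_word_duration = s$duration[1],
       n_words = nrow(s),
       n_sentences = nlevels(key),
       n_phrases = length(unique(s$phrase)),
       total_cry_time = sum(s$duration))
}

#' Write / read a cry structure as tab-separated text
#'
#' One word per line: 0-based phrase, sentence, word indices, onset and
#' duration in seconds. The same dialect as the synthetic ground-truth
#' sidecar, so structures and scripts can be compared file-to-file.
#'
#' @param s a `cry_structure`.
#' @param path file path.
#' @return `write_structure()`: `path` invisibly; `read_structure()`: a
#'   `cry_structure`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "cry_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("phrase\tsentence\tword\tonset_s\tduration_s", con)
  if (nrow(s))
    writeLines(sprintf("%d\t%d\t%d\t%.6f\t%.6f",
                       s$phrase, s$sentence, s$word, s$onset, s$duration), con)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  df <- utils::read.delim(path)
  out <- data.frame(phrase = as.integer(df$phrase),
                    sentence = as.integer(df$sentence),
                    word = as.integer(df$word),
                    onset = df$onset_s, duration = df$duration_s)
  structure(out, class = c("cry_structure", "data.frame"),
            config = segmentation_config())
}
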