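#' Recording metadata record
#'
#' The clinical descriptors attached to each cry recording, mirroring the
#' study database fields, plus the cohort label.
#'
#' @param first_last_name subject name or placeholder.
#' @param number record id.
#' @param indicative group letter plus ordinal, e.g. `"M10"`, `"C7"`.
#' @param sex `"M"` or `"F"`.
#' @param date_of_birth,time_of_birth character timestamps.
#' @param weight_g birth weight, grams (> 0).
#' @param head_circumference_cm,chest_circumference_cm,length_cm
#'   anthropometrics, cm.
#' @param gestational_age_weeks gestational age, weeks (20-45).
#' @param apgar Apgar score, integer 1-10.
#' @param birth_type `"natural"` or `"caesarian"`.
#' @param presentation `"cephalic"`, `"pelvic"` or `"transverse"`.
#' @param gesta,para gravidity / parity counts.
#' @param other_info free text.
#' @param group cohort label, `"M"` (control) or `"C"` (nuchal cord).
#' @return An object of class `recording_metadata`.
#' @export
recording_metadata <- function(first_last_name, number, indicative, sex,
                               date_of_birth, time_of_birth, weight_g,
                               head_circumference_cm, chest_circumference_cm,
                               length_cm, gestational_age_weeks, apgar,
                               birth_type, presentation, gesta, para,
                               other_info = "", group) {
  if (!group %in% c("M", "C")) stop("unknown group: ", group, call. = FALSE)
  if (!sex %in% c("M", "F")) stop("sex must be M or F", call. = FALSE)
  if (!(apgar %in% 1:10)) stop("apgar must be an integer in 1..10",
                               call. = FALSE)
  if (gestational_age_weeks < 20 || gestational_age_weeks > 45)
    stop("gestational_age_weeks must be in [20, 45]", call. = FALSE)
  if (weight_g <= 0) stop("weight_g must be > 0", call. = FALSE)
  if (!grepl("^[MC][0-9]+$", indicative))
    stop("indicative must match [MC][0-9]+", call. = FALSE)
  if (!birth_type %in% c("natural", "caesarian"))
    stop("unknown birth_type: ", birth_type, call. = FALSE)
  if (!presentation %in% c("cephalic", "pelvic", "transverse"))
    stop("unknown presentation: ", presentation, call. = FALSE)
  structure(list(first_last_name = first_last_name, number = number,
                 indicative = indicative, sex = sex,
                 date_of_birth = date_of_birth, time_of_birth = time_of_birth,
                 weight_g = weight_g,
                 head_circumference_cm = head_circumference_cm,
                 chest_circumference_cm = chest_circumference_cm,
                 length_cm = length_cm,
                 gestational_age_weeks = gestational_age_weeks,
                 apgar = as.integer(apgar), birth_type = birth_type,
                 presentation = presentation, gesta = gesta, para = para,
                 other_info = other_info, group = group),
            class = "recording_metadata")
}

#' @export
print.recording_metadata <- function(x, ...) {
  cat(sprintf("<%s: group %s, GA %g wk, Apgar %d, %g g, %s>\n",
              x$indicative, x$group, x$gestational_age_weeks, x$apgar,
              x$weight_g, x$sex))
  invisible(x)
}

#' Cohort inclusion filter
#'
#' Applies the study's inclusion criteria: group M (control) requires
#' gestational age 38-42 weeks and Apgar exactly 10; group C (nuchal cord)
#' requires gestational age >= 38 weeks and Apgar 7-10.
#'
#' @param m a [recording_metadata()].
#' @return List with `include` (logical) and `reason` (`""` when included;
#'   otherwise names the failed criterion, `"GA"` or `"Apgar"`).
#' @export
inclusion_filter <- function(m) {
  stopifnot(inherits(m, "recording_metadata"))
  ga <- m$gestational_age_weeks
  if (m$group == "M") {
    if (ga < 38 || ga > 42)
      return(list(include = FALSE, reason = "GA"))
    if (m$apgar != 10)
      return(list(include = FALSE, reason = "Apgar"))
  } else if (m$group == "C") {
    if (ga < 38)
      return(list(include = FALSE, reason = "GA"))
    if (m$apgar < 7 || m$apgar > 10)
      return(list(include = FALSE, reason = "Apgar"))
  } else stop("unknown group: ", m$group, call. = FALSE)
  list(include = TRUE, reason = "")
}

#' Recording quality filter (noise-based exclusion)
#'
#' Estimates the signal-to-noise ratio of a recording as the ratio (in dB) of
#' the mean VU value over voiced frames to the mean VU value over unvoiced
#' frames, voicing decided by the segmentation activity threshold. Recordings
#' below the threshold, or with no voiced frames at all, are excluded as
#' irreducibly noisy.
#'
#' Voiced frames are the frames covered by detected words; the noise floor is
#' the mean VU of the remaining frames. When noise fills every pause (no
#' unvoiced frame survives the activity threshold) the floor is estimated as
#' the 10th percentile of the trace instead, so heavily contaminated
#' recordings are still rejected rather than scored as noiseless.
#'
#' @param w a [waveform].
#' @param threshold_db minimum acceptable SNR, dB (default 10).
#' @param cfg a [segmentation_config()] providing the activity threshold.
#' @return List with `include` (logical), `snr_db` (estimate; `Inf` when the
#'   unvoiced floor is silent, `NA` when no voiced frames exist) and `reason`.
#' @export
quality_filter <- function(w, threshold_db = 10, cfg = segmentation_config()) {
  vu <- compute_vu(w)
  if (!length(vu$values))
    return(list(include = FALSE, snr_db = NA_real_, reason = "empty"))
  words <- detect_words(vu, cfg)
  if (!nrow(words))
    return(list(include = FALSE, snr_db = NA_real_,
                reason = "no voiced frames"))
  frame_s <- vu$frame_ms / 1000
  voiced <- rep(FALSE, length(vu$values))
  for (i in seq_len(nrow(words))) {
    from <- round(words$onset[i] / frame_s) + 1L
    to <- from + round(words$duration[i] / frame_s) - 1L
    voiced[from:to] <- TRUE
  }
  floor_u <- if (any(!voiced)) mean(vu$values[!voiced]) else
    stats::quantile(vu$values, 0.1, names = FALSE)
  snr_db <- if (floor_u == 0) Inf else
    10 * log10(mean(vu$values[voiced]) / floor_u)
  if (snr_db < threshold_db)
    return(list(include = FALSE, snr_db = snr_db, reason = "low SNR"))
  list(include = TRUE, snr_db = snr_db, reason = "")
}

## ---- Neonat bundle ---------------------------------------------------------

write_meter_txt <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %g", trace$kind, trace$frame_ms), con)
  writeLines(sprintf("%.6f", trace$values), con)
  invisible(path)
}

read_meter_txt <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  new_meter_trace(as.numeric(lines[-1]), hdr[1], as.numeric(hdr[2]))
}

#' Write / read a per-recording measurement bundle
#'
#' Each recording's folder holds one `.wav` file plus three text files: the
#' VU trace, the PPM trace and the short-time spectrum, each with a
#' `# kind frame_ms` header and one frame per line (spectrum frames are
#' tab-separated bin magnitudes).
#'
#' @param dir parent directory; the bundle is written to `dir/name/`.
#' @param name recording name (used for the folder and the wav file).
#' @param w a [waveform].
#' @param vu,ppm `meter_trace`s; computed from `w` when `NULL`.
#' @param spectrum a `spectrum_series`; computed from `w` when `NULL`.
#' @param fft_size FFT size used when `spectrum` is computed here.
#' @return The bundle directory path, invisibly.
#' @export
write_neonat_bundle <- function(dir, name, w, vu = NULL, ppm = NULL,
                                spectrum = NULL, fft_size = 4096) {
  bundle <- file.path(dir, name)
  dir.create(bundle, recursive = TRUE, showWarnings = FALSE)
  vu <- vu %||% compute_vu(w)
  ppm <- ppm %||% compute_ppm(w)
  spectrum <- spectrum %||% compute_spectrum(w, fft_size = fft_size)
  write_wav(w, file.path(bundle, paste0(name, ".wav")))
  write_meter_txt(vu, file.path(bundle, "VU.txt"))
  write_meter_txt(ppm, file.path(bundle, "PPM.txt"))
  con <- file(file.path(bundle, "Spectrum.txt"), "w")
  writeLines(sprintf("# Spectrum %g %g", spectrum$frame_ms,
                     spectrum$bin_width), con)
  if (nrow(spectrum$magnitude))
    writeLines(apply(spectrum$magnitude, 1, function(r)
      paste(sprintf("%.4f", r), collapse = "\t")), con)
  close(con)
  invisible(bundle)
}

#' @rdname write_neonat_bundle
#' @export
read_neonat_bundle <- function(dir) {
  wavs <- list.files(dir, pattern = "\\.wav$", full.names = TRUE)
  if (length(wavs) != 1)
    stop("bundle must contain exactly one wav file: ", dir, call. = FALSE)
  sp_lines <- readLines(file.path(dir, "Spectrum.txt"))
  hdr <- as.numeric(strsplit(sub("^#\\s*Spectrum\\s*", "", sp_lines[1]),
                             "\\s+")[[1]])
  mag <- if (length(sp_lines) > 1) {
    do.call(rbind, lapply(sp_lines[-1], function(ln)
      as.numeric(strsplit(ln, "\t")[[1]])))
  } else matrix(numeric(0), nrow = 0, ncol = 0)
  list(waveform = read_wav(wavs),
       vu = read_meter_txt(file.path(dir, "VU.txt")),
       ppm = read_meter_txt(file.path(dir, "PPM.txt")),
       spectrum = structure(list(magnitude = mag, frame_ms = hdr[1],
                                 bin_width = hdr[2],
                                 freqs = (seq_len(ncol(mag)) - 1) * hdr[2]),
                            class = "spectrum_series"))
}

## ---- Study configuration and runner ----------------------------------------

#' Study configuration
#'
#' Bundles everything [run_study()] needs: per-group synthesis specs, cohort
#' sizes, segmentation config, classifier/evaluation settings, the master
#' seed, and the output directory.
#'
#' @param spec_m,spec_c [synth_spec()] per group (defaults: [cry_preset()]).
#' @param n_m,n_c recordings to generate per group.
#' @param seg a [segmentation_config()].
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed; all randomness derives from it.
#' @param classifiers classifier kinds to evaluate.
#' @param protocols evaluation protocols.
#' @param meters meters used for feature vectors.
#' @param window_s classification window, s.
#' @param snr_threshold_db quality-filter threshold, dB.
#' @param noisy_fraction fraction of generated recordings per group rendered
#'   with `noisy_rms` background noise to exercise the quality filter.
#' @param noisy_rms noise RMS used for injected noisy recordings.
#' @param fft_size FFT size for bundle spectra.
#' @param write_audio write per-recording wav/txt bundles? (Summaries, ARFF
#'   and reports are always written.)
#' @return A `study_config`.
#' @export
study_config <- function(spec_m = cry_preset("M"), spec_c = cry_preset("C"),
                         n_m = 101, n_c = 72,
                         seg = segmentation_config(),
                         out_dir = tempfile("cry_study_"),
                         seed = 1L,
                         classifiers = c("RT", "DT", "IB1", "NNGE"),
                         protocols = c("training", "cv10", "split75"),
                         meters = c("VU", "PPM"),
                         window_s = 30,
                         snr_threshold_db = 10,
                         noisy_fraction = 0,
                         noisy_rms = 0.2,
                         fft_size = 4096,
                         write_audio = TRUE) {
  validate_synth_spec(spec_m)
  validate_synth_spec(spec_c)
  stopifnot(inherits(seg, "segmentation_config"), n_m >= 1, n_c >= 1,
            noisy_fraction >= 0, noisy_fraction <= 1)
  structure(list(spec_m = spec_m, spec_c = spec_c, n_m = n_m, n_c = n_c,
                 seg = seg, out_dir = out_dir, seed = as.integer(seed),
                 classifiers = classifiers, protocols = protocols,
                 meters = meters, window_s = window_s,
                 snr_threshold_db = snr_threshold_db,
                 noisy_fraction = noisy_fraction, noisy_rms = noisy_rms,
                 fft_size = fft_size, write_audio = write_audio),
            class = "study_config")
}

config_hash <- function(cfg) {
  # fingerprint the scientific configuration only: where the outputs land
  # must not change what they contain
  c2 <- unclass(cfg)
  c2$out_dir <- NULL
  fnv1a_hash(paste(deparse(c2), collapse = "\n"))
}

summary_row <- function(s) {
  sprintf("%s\t%d\t%.3f\t%.3f\t%g\t%g", s$variable, s$n, s$mean, s$sd,
          s$min, s$max)
}

#' Run the full synthetic study end-to-end
#'
#' Synthesize the two cohorts, apply the inclusion and quality filters,
#' extract meter traces and spectra, segment every recording, compute the
#' group structural summaries and the intensity table with its t-tests,
#' export ARFF feature files, and evaluate every configured classifier under
#' every protocol. All artifacts are written under `cfg$out_dir`, stamped
#' with the config hash and seed; reruns with the same config are
#' byte-identical.
#'
#' @param cfg a [study_config()].
#' @return Invisibly, a list with `log`, `summaries`, `intensity`
#'   (an [intensity_table()]), `evaluations` (list of `eval_report`),
#'   `included` / `excluded` counts per group, and `out_dir`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("config %s seed %d", config_hash(cfg), cfg$seed)
  log <- c(sprintf("cry study run [%s]", stamp))
  stage <- function(name, rec_id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed for recording %s: %s",
                   name, rec_id, conditionMessage(e)), call. = FALSE))
  }

  groups <- list(M = list(spec = cfg$spec_m, n = cfg$n_m),
                 C = list(spec = cfg$spec_c, n = cfg$n_c))
  records <- list()
  meta_rows <- list()
  counts <- list()
  for (g in names(groups)) {
    n <- groups[[g]]$n
    n_noisy <- round(cfg$noisy_fraction * n)
    included <- 0L; excluded_meta <- 0L; excluded_quality <- 0L
    for (i in seq_len(n)) {
      spec <- groups[[g]]$spec
      if (i > n - n_noisy) spec$noise_rms <- cfg$noisy_rms
      id <- sprintf("%s%d", g, i)
      rec <- stage("synthesis", id,
                   synth_recording(spec, g, i, cfg$seed))
      ok_meta <- stage("inclusion_filter", id, inclusion_filter(rec$metadata))
      if (!ok_meta$include) {
        excluded_meta <- excluded_meta + 1L
        next
      }
      ok_q <- stage("quality_filter", id,
                    quality_filter(rec$waveform, cfg$snr_threshold_db,
                                   cfg$seg))
      if (!ok_q$include) {
        excluded_quality <- excluded_quality + 1L
        log <- c(log, sprintf("excluded %s: %s (snr %.1f dB)", id,
                              ok_q$reason, ok_q$snr_db))
        next
      }
      vu <- stage("meters", id, compute_vu(rec$waveform))
      ppm <- stage("meters", id, compute_ppm(rec$waveform))
      spectrum <- stage("spectrum", id,
                        compute_spectrum(rec$waveform,
                                         fft_size = cfg$fft_size))
      s <- stage("segmentation", id, group_structure(
        detect_words(vu, cfg$seg), cfg$seg))
      if (cfg$write_audio) {
        stage("bundle", id, write_neonat_bundle(
          file.path(cfg$out_dir, "recordings"), id, rec$waveform,
          vu, ppm, spectrum))
        stage("bundle", id, write_cry_script(
          rec$script,
          file.path(cfg$out_dir, "recordings", id, "ground_truth.txt")))
        stage("bundle", id, write_structure(
          s, file.path(cfg$out_dir, "recordings", id, "structure.txt")))
      }
      included <- included + 1L
      records[[id]] <- list(id = id, group = g, metadata = rec$metadata,
                            vu = vu, ppm = ppm, spectrum = spectrum,
                            structure = s,
                            stats = structure_stats(s))
      m <- rec$metadata
      meta_rows[[id]] <- data.frame(
        indicative = m$indicative, group = m$group, sex = m$sex,
        date_of_birth = m$date_of_birth, time_of_birth = m$time_of_birth,
        weight_g = m$weight_g, head_circumference_cm = m$head_circumference_cm,
        chest_circumference_cm = m$chest_circumference_cm,
        length_cm = m$length_cm,
        gestational_age_weeks = m$gestational_age_weeks, apgar = m$apgar,
        birth_type = m$birth_type, presentation = m$presentation,
        gesta = m$gesta, para = m$para)
    }
    counts[[g]] <- list(generated = n, included = included,
                        excluded = excluded_meta + excluded_quality)
    log <- c(log, sprintf(
      "group %s: generated %d, included %d, excluded %d (metadata %d, quality %d)",
      g, n, included, excluded_meta + excluded_quality, excluded_meta,
      excluded_quality))
  }
  if (!length(records)) stop("no recordings survived the filters",
                             call. = FALSE)

  meta_df <- do.call(rbind, meta_rows)
  utils::write.table(meta_df, file.path(cfg$out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  by_group <- split(records, vapply(records, `[[`, "", "group"))
  summaries <- list()
  tbl_lines <- c(sprintf("# structural summaries [%s]", stamp),
                 "variable\tn\tmean\tsd\tmin\tmax")
  for (g in names(by_group)) {
    st <- lapply(by_group[[g]], `[[`, "stats")
    sent <- unlist(lapply(st, `[[`, "sentence_durations"))
    wps <- unlist(lapply(st, `[[`, "words_per_sentence"))
    fw <- vapply(st, `[[`, numeric(1), "first_word_duration")
    summaries[[g]] <- list(
      sentence_duration = summarize_variable(sent,
                                             paste0(g, ".sentence_duration_s")),
      words_per_sentence = summarize_variable(wps,
                                              paste0(g, ".words_per_sentence")),
      first_word_duration = summarize_variable(
        fw[!is.na(fw)], paste0(g, ".first_word_duration_s")))
    tbl_lines <- c(tbl_lines, vapply(summaries[[g]], summary_row, ""))
  }
  writeLines(tbl_lines, file.path(cfg$out_dir, "structure_summaries.tsv"))

  intensity <- intensity_table(by_group$M, by_group$C, cfg$seg)
  int_lines <- c(sprintf("# intensity table [%s]", stamp),
                 "group\tmeter\tn\tmean_u\tmin_u\tmax_u\tmean_min_u",
                 sprintf("%s\t%s\t%d\t%.3f\t%.3f\t%.3f\t%.3f",
                         intensity$group, intensity$meter, intensity$n,
                         intensity$mean_u, intensity$min_u, intensity$max_u,
                         intensity$mean_min_u))
  tt <- attr(intensity, "t_tests")
  for (m in names(tt))
    int_lines <- c(int_lines, sprintf(
      "# t-test %s mean minimums M vs C: t=%.4f df=%.2f p=%.6g %s",
      m, tt[[m]]$t, tt[[m]]$df, tt[[m]]$p,
      if (tt[[m]]$significant) "significant" else "ns"))
  writeLines(int_lines, file.path(cfg$out_dir, "intensity_table.tsv"))

  evaluations <- list()
  for (meter in cfg$meters) {
    d <- build_feature_vectors(unname(records), meter, cfg$window_s)
    write_arff(d, file.path(cfg$out_dir,
                            sprintf("features_%s.arff", tolower(meter))))
    for (kind in cfg$classifiers) {
      rep_lines <- c(sprintf("# classifier %s on %s [%s]", kind, meter, stamp),
                     "indicator\ttraining\tcv10\tsplit75")
      reports <- lapply(cfg$protocols, function(pr)
        evaluate_classifier(kind, d, pr, seed = cfg$seed))
      names(reports) <- cfg$protocols
      fields <- c("correctly_classified_pct", "incorrectly_classified_pct",
                  "mean_absolute_error", "root_mean_squared_error",
                  "relative_absolute_error_pct",
                  "root_relative_squared_error_pct")
      for (f in fields) {
        vals <- vapply(cfg$protocols, function(pr)
          sprintf("%.4f", reports[[pr]][[f]]), "")
        rep_lines <- c(rep_lines, paste(c(f, vals), collapse = "\t"))
      }
      for (pr in cfg$protocols) {
        cm <- reports[[pr]]$confusion_matrix
        rep_lines <- c(rep_lines, sprintf(
          "confusion_%s\t%s", pr,
          paste(sprintf("%s->%s:%d",
                        rep(rownames(cm), each = ncol(cm)),
                        rep(colnames(cm), times = nrow(cm)),
                        as.integer(t(cm))), collapse = " ")))
      }
      writeLines(rep_lines, file.path(cfg$out_dir, sprintf(
        "classify_%s_%s.tsv", tolower(meter), tolower(kind))))
      evaluations[[sprintf("%s_%s", meter, kind)]] <- reports
    }
  }

  writeLines(log, file.path(cfg$out_dir, "study_log.txt"))
  invisible(list(log = log, summaries = summaries, intensity = intensity,
                 evaluations = evaluations, counts = counts,
                 out_dir = cfg$out_dir))
}
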