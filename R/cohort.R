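#' Descriptive summary of one variable
#'
#' Sample mean, sample SD (n-1 denominator), minimum, maximum and count — the
#' layout of the study's descriptive tables.
#'
#' @param values numeric vector, `n >= 1`, no missing values.
#' @param name variable name carried in the output.
#' @return A `cohort_summary`: list with `variable`, `n`, `mean`, `sd`,
#'   `min`, `max` (`sd` is 0 for a single observation).
#' @examples
#' summarize_variable(c(4, 18), "words_per_sentence")
#' @export
summarize_variable <- function(values, name = "variable") {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (any(is.na(values))) stop("missing values not allowed", call. = FALSE)
  structure(list(variable = name,
                 n = length(values),
                 mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 min = min(values),
                 max = max(values)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s: N=%d  mean=%.3f  sd=%.3f  min=%g  max=%g\n",
              x$variable, x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Two-sample t-test between cohorts
#'
#' Two-sided two-sample t-test with a 95% confidence interval for the mean
#' difference. Student's pooled-variance test is the default, matching the
#' study's analysis; `welch = TRUE` requests the Welch variant, and
#' `welch = "auto"` upgrades to Welch (with a message) when the sample
#' variance ratio exceeds 4.
#'
#' Degenerate inputs follow the conventions: two groups with zero pooled
#' variance and equal means give `t = 0, p = 1`; zero pooled variance with
#' unequal means is an error.
#'
#' @param a,b numeric vectors, each with `n >= 2`.
#' @param alpha significance level for the `significant` flag.
#' @param welch `FALSE` (Student, default), `TRUE` (Welch) or `"auto"`.
#' @return A `cry_ttest`: list with `t`, `df`, `p`, `conf_int` (95% CI of
#'   `mean(a) - mean(b)`), `mean_a`, `mean_b`, `significant`, `alpha`,
#'   `method`.
#' @export
group_t_test <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  conf_int = c(0, 0), mean_a = mean(a), mean_b = mean(b),
                  significant = FALSE, alpha = alpha,
                  method = "Student (degenerate: zero variance)")
      return(structure(res, class = "cry_ttest"))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  if (identical(welch, "auto")) {
    ratio <- max(va, vb) / max(min(va, vb), .Machine$double.eps)
    welch <- ratio > 4
    if (welch)
      message(sprintf(
        "variance ratio %.2f > 4: using Welch's t-test", ratio))
  }
  ht <- stats::t.test(a, b, var.equal = !welch, conf.level = 0.95)
  structure(list(t = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 conf_int = as.numeric(ht$conf.int),
                 mean_a = mean(a), mean_b = mean(b),
                 significant = ht$p.value < alpha,
                 alpha = alpha,
                 method = if (welch) "Welch" else "Student"),
            class = "cry_ttest")
}

#' @export
print.cry_ttest <- function(x, ...) {
  cat(sprintf(
    "%s t-test: t=%.4f df=%.2f p=%.4g (95%% CI %.3f..%.3f) %s at alpha=%g\n",
    x$method, x$t, x$df, x$p, x$conf_int[1], x$conf_int[2],
    if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

# per-recording voiced-frame summaries for one meter; `recs` is a list of
# lists with elements vu / ppm / spectrum (traces) as built by the study
# runner or tests
meter_values <- function(rec, meter) {
  switch(meter,
         VU = rec$vu$values,
         PPM = rec$ppm$values,
         Spectrum = {
           if (is.null(rec$spectrum)) return(NULL)
           apply(rec$spectrum$magnitude, 1, max)
         },
         stop("unknown meter: ", meter, call. = FALSE))
}

#' Group intensity table with mean-minimum t-tests
#'
#' For each group and meter: the group mean of per-recording voiced-frame
#' means, the global voiced-frame min-max range, and the group mean of the
#' per-recording minima ("mean minimums", the study's headline discriminating
#' statistic). Student t-tests comparing per-recording minima between the
#' groups are attached for VU and PPM.
#'
#' Voicing is decided on each recording's VU trace with the activity
#' threshold of `cfg`, so minima describe the quietest cry-active frame, not
#' silence between bursts.
#'
#' @param recs_m,recs_c lists of per-recording trace sets; each element needs
#'   `$vu` and `$ppm` `meter_trace`s and optionally `$spectrum`
#'   (a `spectrum_series`).
#' @param cfg a [segmentation_config()] providing the activity threshold.
#' @param meters character subset of `c("VU", "PPM", "Spectrum")`.
#' @param alpha significance level for the attached t-tests.
#' @return An `intensity_table`: data.frame with one row per group x meter
#'   (`group`, `meter`, `n`, `mean_u`, `min_u`, `max_u`, `mean_min_u`) and an
#'   attribute `t_tests` (named list of `cry_ttest` for VU/PPM per-recording
#'   minima, M vs C).
#' @export
intensity_table <- function(recs_m, recs_c, cfg = segmentation_config(),
                            meters = c("VU", "PPM", "Spectrum"),
                            alpha = 0.05) {
  per_rec <- function(rec, meter) {
    vu_vals <- rec$vu$values
    thr <- cfg$activity_threshold %||% default_activity_threshold(vu_vals)
    voiced <- vu_vals > thr
    vals <- meter_values(rec, meter)
    if (is.null(vals)) return(NULL)
    vals <- vals[voiced]
    if (!length(vals))
      stop("recording has no voiced frames", call. = FALSE)
    c(mean = mean(vals), min = min(vals), max = max(vals))
  }
  groups <- list(M = recs_m, C = recs_c)
  rows <- list()
  minima <- list()
  for (g in names(groups)) {
    for (meter in meters) {
      sm <- lapply(groups[[g]], per_rec, meter = meter)
      sm <- sm[!vapply(sm, is.null, logical(1))]
      if (!length(sm)) next
      m <- do.call(rbind, sm)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, meter = meter, n = nrow(m),
        mean_u = mean(m[, "mean"]),
        min_u = min(m[, "min"]),
        max_u = max(m[, "max"]),
        mean_min_u = mean(m[, "min"]))
      minima[[paste(g, meter)]] <- m[, "min"]
    }
  }
  out <- do.call(rbind, rows)
  tt <- list()
  for (meter in intersect(c("VU", "PPM"), meters)) {
    a <- minima[[paste("M", meter)]]
    b <- minima[[paste("C", meter)]]
    if (!is.null(a) && !is.null(b) && length(a) >= 2 && length(b) >= 2)
      tt[[meter]] <- group_t_test(a, b, alpha = alpha)
  }
  structure(out, t_tests = tt, class = c("intensity_table", "data.frame"))
}

#' @export
print.intensity_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 6)
  tt <- attr(x, "t_tests")
  for (m in names(tt)) {
    cat(sprintf("%s per-recording minima, M vs C: ", m))
    print(tt[[m]])
  }
  invisible(x)
}
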