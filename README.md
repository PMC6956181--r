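# cryspect

Quantitative analysis of newborn cry recordings, built around the idea that
a cry is structured like language: one expiratory vocalization is a *word*,
a cry burst is a *sentence*, and a group of bursts is a *phrase*. The
package targets the comparison of two neonatal cohorts — control newborns
versus newborns delivered with a tight nuchal cord — whose cries differ not
in their loudest moments but in their quietest ones.

## What it computes

* **Intensity metering.** Two meters on a 100 ms grid, in the PCM-magnitude
  unit U (`U = |round(sample × 32767)|`): the VU meter (per-frame mean,
  average loudness) and the PPM meter (per-frame maximum, peak loudness),
  plus Hann-windowed short-time magnitude spectra and an autocorrelation F0
  track for the 250–450 Hz newborn fundamental.
* **Cry-to-language segmentation.** Words are maximal runs of VU frames
  above an activity threshold (default `max(50 U, 5% of trace max)`);
  silences up to 1 s group words into sentences, up to 3 s group sentences
  into phrases. Per-recording statistics: sentence durations,
  words/sentence, first-word duration.
* **Cohort statistics.** Descriptive n/mean/SD/min/max tables and
  Student/Welch two-sample t-tests (95% CI). The headline statistic is the
  *mean minimum*: per recording, the quietest voiced meter frame; per
  group, the mean of these minima.
* **Classification study.** 300-attribute feature vectors (30 s × 10
  frames/s of VU or PPM) with ARFF import/export, four classifiers (random
  tree, decision table, 1-nearest-neighbour, nearest-generalized-exemplar)
  and three protocols (training set, stratified 10-fold CV, 75/25 split),
  reporting six quality indicators and the confusion matrix.
* **Synthetic cohorts.** A scripted cry generator (harmonic-stack words,
  controlled burst/pause hierarchy, group presets for words-per-sentence
  distributions and minimum-intensity levels) so the entire pipeline is
  testable without clinical audio, plus `run_study()` to execute the whole
  study end-to-end and write every artifact.

## Worked example

```r
library(cryspect)

## script and render one control-group cry (20-30 s), no background noise
spec   <- cry_preset("M", total_duration_range = c(20, 30), noise_rms = 0)
script <- plan_cry(spec, rng_seed = 42)
script
#> <cry_script: 11 words, 1 sentences, 1 phrases, 29.1 s>
w <- render_cry(script, spec)

## meter it and segment it back into words/sentences/phrases
vu <- compute_vu(w)
vu
#> <VU trace: 291 frames x 100 ms, range [0.0, 10705.8] U>
st <- structure_stats(segment_cry(w))
st$words_per_sentence
#> [1] 11                      # exactly the scripted count
st$first_word_duration
#> [1] 1.2                     # seconds

## voiced-frame intensity summary (mean with min-max range, in U)
summarize_trace(vu)
#> <trace summary: mean 6778.648 U (3434-10706 U), 148 frames>

## the headline group test: per-recording minimum VU at the two cohorts'
## mean-minimum levels (control 11 U vs nuchal cord 24 U, CV 0.5)
set.seed(2)
group_t_test(sample_min_intensity(101, 11, 0.5),
             sample_min_intensity(72, 24, 0.5))
#> Student t-test: t=-10.1378 df=171.00 p=3.292e-19
#>   (95% CI -17.079..-11.512) significant at alpha=0.05
```

The scripted word count comes back exactly because word boundaries live on
the 100 ms meter grid and the recording is noise-free; the t-test shows the
nuchal-cord group's elevated minimum intensity is highly significant at the
study's sample sizes.

For a full study — cohorts, filters, summaries, t-tests, ARFF files and
classifier reports written to a directory — see `?run_study`, or use the
command-line front end in `inst/scripts/cryspect.R`. The methods vignette
(`vignettes/cry-analysis-methods.Rmd`) documents the measurement model, the
segmentation defaults, the generator's presets and the package's known
limitations.

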