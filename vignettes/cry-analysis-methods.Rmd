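---
title: "Methods: measuring, segmenting and classifying the newborn cry"
author: "cryspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring, segmenting and classifying the newborn cry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryspect)
```

## The measurement model

A newborn cry is an alternation of expiratory vocalizations and inhalation
pauses. `cryspect` measures a mono recording on a fixed 100 ms grid with two
meters:

* **VU** (volume unit): the mean of the absolute 16-bit PCM sample
  magnitudes in each frame — average loudness;
* **PPM** (peak programme): the maximum absolute PCM magnitude per frame —
  peak loudness.

Both are expressed in the unit **U**, defined here as
`U = |round(sample × 32767)|`, i.e. 16-bit PCM magnitude: a full-scale
signal meters 32767 U, a full-scale sinusoid has VU ≈ (2/π)·32767 ≈ 20860 U.
U is an app-style arbitrary unit, deliberately not dB or Hz; defining it on
the PCM scale reproduces the orders of magnitude seen in practice for cry
recordings (per-frame VU in the hundreds-to-thousands) while staying exactly
computable from the samples. Meter frames are rectangular and
non-overlapping (one value per 100 ms); a trailing partial frame is
dropped.

Alongside the meters, `compute_spectrum()` gives a Hann-windowed,
zero-padded short-time magnitude spectrum scaled so a full-scale sinusoid
peaks near 32767 U, and `estimate_f0()` tracks the fundamental frequency by
autocorrelation with parabolic peak interpolation, restricted to a search
band (default 150–800 Hz, bracketing the ≈250–450 Hz fundamental of healthy
newborns). Autocorrelation is sufficient here because the voiced frames are
strongly harmonic; no attempt is made to track hyperphonation or
biphonation.

## The cry-to-language segmentation

The cry is described as language: one expiration is a **word**, a cry burst
is a **sentence**, a group of bursts is a **phrase**. Segmentation runs on
the VU trace, not the raw audio, because the 100 ms meters are the native
representation of the measurement model; its time resolution is therefore
one frame (100 ms), which we accept.

* A word is a maximal run of frames with VU above the **activity
  threshold**. Default threshold: `max(50 U, 5% of the trace maximum)` — an
  absolute floor against quantization-level noise plus a relative floor so
  the rule adapts to the recording level. Runs shorter than `min_word_ms`
  (default 200 ms) are discarded as clicks.
* Words separated by silence ≤ `sentence_gap_ms` (default 1000 ms; an
  inhalation between expirations is shorter than this) share a sentence.
* Sentences separated by silence ≤ `phrase_gap_ms` (default 3000 ms) share
  a phrase.

The three thresholds are configurable (`segmentation_config()`); the strict
ordering `intra-word gap < sentence pause < phrase pause` in the generator
guarantees the hierarchy is well-posed under the defaults. Coordinates are
seconds, half-open intervals, 0-based indices.

Whole-recording intensity summaries (`summarize_trace()`,
`intensity_table()`) restrict to *voiced* frames — frames above the
activity threshold — because the minimum over an entire recording would
otherwise always be the silence between bursts (≈0 U). The per-recording
minimum voiced value is the quietest cry-active frame, and the group mean
of these minima ("mean minimums") is the study's headline discriminating
statistic. For spectra the per-frame scalar summarized is the maximum bin
magnitude (peak spectral intensity); voicing is always decided on the VU
trace so all meters are summarized over the same frames.

## The synthetic cohort generator

Clinical cry recordings cannot be redistributed, so all testing runs on a
generative stand-in with scripted ground truth. The generator is
deliberately minimal: it must support exactly the features the pipeline
measures (meter levels, a harmonic spectrum in the newborn F0 band, and the
burst/pause hierarchy), not vocal-tract physiology. Formants and
pathological cry modes are out of scope.

`plan_cry()` samples a `cry_script`:

* total duration uniform in `total_duration_range` (default 30–90 s, the
  recording protocol's range);
* sentences per phrase uniform in a small integer range (default 1–3; no
  published counts exist, this is a free choice);
* **words per sentence** from a discrete normal (rounded, clipped to the
  configured range). The group presets use the published distribution
  parameters: control (M) mean 9.45, SD 3.381, range 4–18; nuchal cord (C)
  mean 7.65, SD 2.485, range 4–14. Clipping (rather than rejection
  resampling) is used because it perturbs the mean less (+0.07 words for
  the M parameters);
* word durations from a clipped normal with mean 1.0 s over the population
  range 0.5–2.9 s (SD = range span / 4; no SD is published). The
  recording's **first word** has its own distribution, mean 1.21 s
  (SD 0.4 s, a free choice), reflecting the longer first expiration;
* a per-word F0 around the preset mean (350 Hz, jitter 5%), and per-word
  intensity levels (below).

All onsets, durations and pauses are quantized to the 100 ms meter grid, so
the script and the meter-domain segmentation are commensurate: with zero
noise the round trip *render → VU → segment* recovers the scripted counts
exactly, which is the package's strongest structural test. Trailing
structure that does not fit the drawn duration is truncated at **sentence
boundaries** — a sentence is only ever emitted whole — because partial
sentences would bias pooled words-per-sentence statistics downward. (The
flip side is a mild selection effect: long sentences are slightly less
likely to fit the tail of a recording, so recovered cohort means sit a few
tenths below the sampler mean; this is visible in the acceptance numbers
and accepted.) If even the first word does not fit, a single word truncated
to the budget is emitted.

`render_cry()` renders each word as a zero-phase harmonic stack (default 5
partials, 1/k roll-off, normalized to unit peak) under a 15 ms attack /
30 ms decay linear envelope, plus optional Gaussian background noise;
output is clipped to [−1, 1].

### Intensity levels and the U scale of the presets

Word levels are drawn from a lognormal with the preset mean and a
coefficient of variation of 0.5 (the published tables give means and ranges
but no dispersion; the CV is an explicit free parameter,
`amplitude_cv`). Each recording draws a minimum-level target, and its
quietest word is forced to that level, so the distribution of per-recording
minima — the statistic the study turns on — is controlled directly.

The original app's absolute U scale is not recoverable, and the published
summary levels are internally inconsistent with any threshold-based
segmentation: the published per-recording minimum VU levels (11 U control,
24 U nuchal cord) are ≈3% of the published group mean VU (365/439 U), below
the 5%-of-maximum activity floor, so words that quiet would be undetectable
by the very segmentation that defines them. The presets therefore preserve
the *ordering and approximate ratios* of the published levels while keeping
every word detectable: sustain means 7300 U (M) and 8770 U (C), minimum
levels 2200 U (M) and 4800 U (C). The published absolute minima are used
unchanged where they are actually compared: the statistical replication of
the group test draws per-recording minima at exactly 11 vs 24 U (VU) and
343 vs 598 U (PPM) via `sample_min_intensity()`.

Default rendering is 22 050 Hz, 16-bit PCM — ample for a sub-500 Hz
fundamental plus a handful of harmonics; no rate is prescribed by the
recording protocol.

## Cohort statistics

`summarize_variable()` reports n / mean / sample SD / min / max, the layout
of the study's descriptive tables. `group_t_test()` is a two-sided
two-sample t-test with a 95% CI; Student's pooled-variance form is the
default (matching the study), Welch is available, and `welch = "auto"`
upgrades with a message when the variance ratio exceeds 4. Two primary
endpoints (VU and PPM mean minimums) are tested without multiplicity
correction, again matching the study design. Degenerate inputs follow
explicit conventions: zero variance with equal means gives t = 0, p = 1;
zero variance with unequal means is an error.

`intensity_table()` computes, per group and meter, the group mean of
per-recording voiced-frame means, the global voiced min–max range, and the
mean of per-recording minima, attaching the M-vs-C t-tests for VU and PPM.
It defaults to per-recording statistics; the published table's "(sentences)"
annotation is ambiguous between per-recording and per-sentence units, and
per-recording is the only reading consistent with a single minimum per
subject entering a group mean.

One published descriptive (sentence duration ≈11.9 per control recording)
carries no units; treated as seconds it is roughly consistent with ~9.5
words of ~1 s plus inhalation gaps, and the generator's defaults land in
that region, but nothing downstream depends on it.

## The classification study

`build_feature_vectors()` turns the first 30 s of a meter trace into a
300-attribute vector (10 frames/s × 30 s), truncating longer recordings and
right-padding shorter ones with 0 U — silence is the only meter-neutral
padding. Attributes are raw U values by default (nothing suggests the
original study normalized them). Datasets round-trip through standard ARFF
(`write_arff()` / `read_arff()`), with numerics printed at 17 significant
digits so doubles survive exactly.

Four classifier families are implemented in-package as documented,
simplified-faithful variants of the classical algorithms (exact numeric
parity with any particular toolkit is a non-goal since the original data
are unavailable):

* **RT** — random tree: unpruned; at each node the best information-gain
  split among `K = ⌈log2(p) + 1⌉` randomly sampled attributes (all
  attributes reconsidered if none of the sample gains), grown to purity;
* **IB1** — single Euclidean nearest neighbour, first-found tie-break;
* **DT** — decision table over quantile-binned attributes chosen by greedy
  forward selection on leave-one-out accuracy, majority-class default for
  unmatched rows. On very small data LOO cannot rank attributes (every
  held-out singleton cell is empty), so the fallback keeps the single best
  attribute by resubstitution;
* **NNGE** — nearest-neighbour with generalized exemplars: instances are
  absorbed into axis-aligned hyperrectangles of their class; a
  generalization that would swallow an opposite-class point is rejected,
  and a conflict (a point inside an opposite-class rectangle) shrinks that
  rectangle along its cheapest face.

`evaluate_classifier()` implements the three study protocols — training-set
evaluation, stratified seeded 10-fold cross-validation (predictions pooled
over folds), and a stratified seeded 75/25 split — and six quality
indicators: correctly/incorrectly classified percentages (always summing to
100), MAE and RMSE of the class-probability vectors against one-hot truth,
and the relative errors RAE and RRSE normalized by a prior-probability
baseline fitted on the corresponding training data. The study's
translated indicator names ("average relative/absolute error", "average/
absolute square error") map onto this canonical Weka quartet, the only
four-error set consistent with its report layout. The 2×2 confusion matrix
accompanies every report. The "1B1" classifier name is read as IB1, and the
rule-based/lazy category labels attached to IB1 and NNGE are treated as
swapped.

On the synthetic cohorts the training protocol reproduces the analytic
expectations exactly — a memorizing learner (IB1, or an unpruned tree grown
to purity) scores 100% on duplicate-free training data — while
cross-validated accuracy depends on how separable the two groups' intensity
distributions are made.

## Problem sizes, tolerances and determinism

The test suite and the acceptance analysis synthesize full-size cohorts
(101 M + 72 C recordings of 30–90 s at 22 050 Hz) for the parameter-recovery
checks — about a minute of compute — and smaller scripted fixtures (5–15 s
recordings) for structural unit tests. Sampling tolerances follow from the
published dispersions: pooled words-per-sentence means are recovered within
±0.5 words (SE ≈ 0.17 at ~400 pooled sentences), the pooled first-word mean
within ±0.1 s. The replicated minimum-intensity t-tests are extremely well
powered at the published levels (t ≈ 7–9), so the p < 0.05 threshold is met
in ≥95 of 100 replicates with large margin; a 1000-shuffle label
permutation confirms the test's type-I error stays at 5% ± 2 points.

All randomness flows from integer seeds: per-recording seeds derive
deterministically from a master seed, so cohorts, studies and evaluation
reports are reproducible bit-for-bit (`run_study()` writes byte-identical
output bundles on reruns, stamped with a config hash and the seed).

## Known limitations

* The generator emulates meter-level structure, not cry acoustics: no
  formants, no intonation contours, no inspiratory sounds, no pathological
  phonation modes. Passing round-trip tests show the *pipeline* is correct,
  not that real recordings would separate as cleanly.
* Segmentation resolution is one meter frame (100 ms); words shorter than
  `min_word_ms` are invisible by design.
* The U scale is this package's definition; absolute U values are not
  comparable with the original app's beyond ordering and rough ratios.
* Group separability of the synthetic cohorts is an assumption encoded in
  the presets, so cross-validated classifier accuracies on synthetic data
  characterize the implementation, not the clinical effect size.
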