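---
title: "Estimating fetal autonomic age from beat-to-beat heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fetal autonomic age from beat-to-beat heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabas)
```

## The problem

Fetal heart rate patterns are one of the few windows onto the developing
autonomic nervous system. As the fetus matures from mid-gestation to term,
three universal developmental signatures appear in the beat-to-beat (NN)
interval series: the fluctuation amplitude grows, the signal becomes more
complex, and characteristic patterns form — behavioral states alternate
between quiet and active sleep, and accelerations (AC) become more
pronounced while decelerations (DC) recede. `fabas` turns these signatures
into a *fetal autonomic brain age score*: a regression estimate of
gestational age from heart rate variability (HRV) indices, computed from
millisecond-resolution beat interval recordings such as those produced by
fetal magnetocardiography. The gap between scored and chronological age,
referenced against a normogram, is the quantity of clinical interest.

The package implements the full chain: CTG-compatible short- and long-term
variability with the Dawes-Redman normality criteria (the clinical
comparator), the five maturation indices, rule-based behavioral-state
segmentation, AC/DC pattern segmentation within quiet sleep, stepwise
weighted regression age models, and normograms — plus a seeded synthetic
recording generator that provides ground truth for every stage.

## Input model

A recording is a validated `nn_series`: beat onset times (s), NN intervals
(ms), and a per-interval validity flag. Artifacts are *flagged, never
deleted*, because the clinical rules reason about artifact fractions (a
minute with more than 50% artifact is not analyzable; the normality
criteria check total signal loss below 30%, measured here as invalid time
fraction). Segments and windows are half-open `[start, end)` with
membership by beat onset, so adjacent segments partition the beats. Invalid
beats are omitted from the indices (no interpolation); pairs that would
span an invalid interval are excluded from difference-based measures.

## CTG-compatible analysis

Clinical CTG integrates intervals over 3.75 s epochs, 16 per minute.
`epoch_series()` computes time-weighted epoch means of the valid intervals;
`stv()` is the mean absolute difference of consecutive epochs within
analyzable minutes, averaged across minutes, and `ltv()` the mean per-minute
fluctuation range: maximal deviation above the baseline plus maximal
deviation below it, on the interval (ms) scale, with the bpm baseline
converted at its own value.

The published Dawes-Redman baseline algorithm is proprietary, so
`estimate_baseline()` substitutes a transparent iterated trimmed moving
median: a 3-min centered median in bpm, exclusion of samples deviating more
than 10 bpm, refit, to convergence or five passes. The method tag travels
with the output so a different estimator can be plugged in auditable.

Event detection applies the CTG definitions: an AC is more than 10 bpm
above baseline for more than 15 s; a DC is below baseline for more than
30 s at a deviation above 20 bpm, or more than 60 s above 10 bpm. Lost
beats are the time integral of the bpm deficit over a DC divided by 60.
Two numerical choices matter on beat-level data and are deliberate detector
features, not spec items: the deviation is median-filtered over ~2 s, and
candidate runs separated by less than 5 s are merged before the gates are
applied. Without them, white beat-to-beat jitter fragments every excursion
and the written definitions detect nothing on realistic traces; both
constants are arguments.

The nine normality criteria are evaluated independently with evidence
strings; the overall verdict is their conjunction and indeterminate
criteria (e.g. a missing LTV reference table) count as not passed.
Conventions the criteria text leaves open, each configurable:

* *Episode of high variation*: a maximal run of at least 6 minutes in which
  at least 5 of any 6 consecutive minutes have a fluctuation range above
  32 ms (threshold borrowed from the Dawes-Redman literature).
* *Sinusoidal rhythm*: flagged when more than 60% of 0.02-0.2 Hz power
  falls in one spectral mainlobe (peak bin plus neighbours) of the
  resampled tachogram.
* *Large deceleration* for minute exclusion: more than 20 lost beats,
  reusing the smallest criterion bound.
* Basal rate = median of the baseline; signal loss counts time, not
  epochs; the final-epoch criterion also fails when the recording ends in
  majority artifact.
* Reference percentiles of episode LTV by week are not published in
  machine-readable form; the packaged table is synthetic (see
  `inst/extdata/ltv_reference_synthetic.csv`) and
  `derive_reference_percentiles()` builds a real one from a cohort.

## The five maturation indices

* **AMP** — 20-95 inter-quantile distance (linear-interpolation quantiles)
  of the locally detrended NN series. The 60 s moving-average detrending
  window keeps state transitions and baseline drift out of the amplitude
  while passing the sympatho-vagal band.
* **skewness** — bias-uncorrected sample skewness `m3 / m2^1.5` of the
  instantaneous heart rate (60000/NN of the valid beats). DC push it
  negative, AC positive, so it tracks the decline of decelerations and the
  formation of accelerations with maturation.
* **pNN5** — percentage of array-adjacent valid interval pairs differing by
  strictly more than 5 ms; a vagal marker. A 5.000 ms difference is not
  counted.
* **lnVLF/LF** — log ratio of 0.02-0.08 Hz to 0.08-0.2 Hz band power of
  the tachogram, cubic-spline resampled at 4 Hz, Welch-averaged
  periodogram with Hann taper, 150 s segments, 50% overlap, mean removal
  per segment (the band edges are fixed; the estimator settings are
  defaults recorded with the result). Computed on the un-detrended,
  mean-removed tachogram.
* **gMSE3** — complexity at coarse-graining level 3: non-overlapping means
  of 3 consecutive intervals (multiscale convention, `floor(N/3)` values),
  then auto mutual information at lag 1 by equiprobable rank-based binning
  with `B = floor(sqrt(M/5))` bins over the `M` lagged pairs, in nats.
  Rank binning makes the estimator invariant under monotone transformations
  of the (coarse) values; the plug-in estimate is non-negative and carries
  a positive bias of order `(B-1)^2 / (2M)` that the permutation-null
  calibration test bounds in practice. All estimator settings are recorded
  in the result's attributes. The default minimum of 300 valid intervals is
  relaxed to 120 for the 3-minute pattern windows, recorded in the output.

## Behavioral-state segmentation

The reference classification in this field is an expert consensus; the
package operationalises the written rules as a transparent engine and
exports every evidence number so a human can overrule it with an
annotation file. A 10-min window is quiet sleep (HRP I) when the floating
baseline (3-min trimmed moving median) drifts less than 10 bpm per 3 min,
the oscillation bandwidth stays below ±5 bpm, at most 2 AC (>15 bpm for
>15 s) occur, and the baseline never exceeds 160 bpm; active sleep
(HRP II) when the bandwidth exceeds ±5 bpm with at least 3 AC and the rate
exceeds 160 bpm only during AC; active awakeness (HRP III) on sustained
tachycardia. Open points, resolved as documented conventions:

* Bandwidth = half the 2.5-97.5 percentile span of the median-smoothed
  deviation, measured *between* AC/DC complexes: all >10 bpm excursions are
  masked with a 10 s shoulder, mirroring how a clinician reads the band.
* "fHR above 160 only during AC" vs "sustained tachycardia" are made
  complementary at 60 s above 160 bpm outside AC.
* Rules are evaluated as exclusive hits; conflicts give `unclassified`.
* When a state persists longer than 10 min, the selected segment maximises
  the rule margin: smallest bandwidth for quiet, largest for active, ties
  to the earliest window (sliding 10-min windows, 1-min step).

## Pattern segmentation in quiet sleep

Within a selected 600 s quiet segment, eight 180 s windows shifted by 60 s
are flagged against their own window median: `has_dc` when any (smoothed)
sample drops more than 10 bpm below it, `has_ac` symmetrically above — a
single sample suffices by default (`min_excursion_s = 0` takes the written
rule literally; raise it when validity flags are unreliable). Four indices
(skewness, pNN5, lnVLF/LF, gMSE3) are computed per qualifying window and
averaged: the *w/o DC* variant keeps windows without DC, the *basic*
variant windows with neither AC nor DC — always a subset. AMP has no
segmented variant.

## Age models and normograms

Rows are weighted by the inverse of their completed-week bin count,
normalised to mean 1, approximating a uniform age distribution; weights
are treated as analytic weights throughout. `stepwise_fit()` runs
forward/backward selection on weighted least squares: the forward step
admits the candidate with the smallest partial-F p-value below 0.05, the
backward step removes any included predictor above 0.10, iterated to a
fixed point; the quadratic variant augments the candidate set with squared
centered terms (centers stored with the model so prediction reproduces the
training design). Adjusted R² is reported on the weighted fit. Note that
with several candidates the probability that *some* noise predictor enters
exceeds the per-test 0.05 — the selection is deliberately uncorrected, as
in the standard stepwise procedures of mainstream statistics packages; the
calibration test therefore measures the false-entry rate with a single
candidate.

Normograms report the weighted mean ± SD of the score in weekly bins, with
21-24 and 37-40 weeks merged where cohorts are sparse;
`score_deviation()` returns the z-score of a recording against its bin.
The package ships no fitted coefficients: models are fitted on user or
synthetic cohorts.

## The synthetic generator — what it does and does not emulate

`generate_recording()` is a test fixture, not a physiological model: a
baseline heart rate declining 150→135 bpm over 21→40 weeks, state-dependent
AR(1) modulation (quiet SD 0.9→1.4 bpm, ×3 in active sleep), 0.05/0.15 Hz
sinusoids, flat-topped AC/DC bumps, white beat-to-beat interval jitter
(1.5→4 ms), and flagged artifact spans; beats are obtained by stepping
through the instantaneous rate. Each index has exactly one designed driver
(AMP ← modulation depth, pNN5 ← jitter, lnVLF/LF ← band amplitudes,
gMSE3 ← AR coefficient 0.62→0.95, skewness ← AC growth and DC decline),
all maps smooth and monotone so recovery tests have a defined direction.
States are planted as quiet `[0, 900)` / active `[900, 1800)` by default
with deterministic, interleaved event placement, keeping planted windows at
stable rule margins; Poisson event counts are available via
`poisson_events = TRUE`. Per-recording log-normal multipliers (SD 0.08) and
a ±2 bpm baseline offset supply inter-individual variation.

What passing tests show — and do not show. The generator's
inter-individual noise is mild, so fitted adjusted R² on synthetic cohorts
(≈0.9) is far higher than anything reported on real cohorts (≈0.2-0.7);
synthetic results validate the *machinery* (detectors hit their planted
targets, estimators match oracles, selection is calibrated), not clinical
performance. Real recordings have non-stationary states, ectopy,
maternal-signal residue and movement artifacts that the generator does not
emulate.

Problem sizes used in the shipped checks were chosen for tight feedback
loops at desk scale: oracle comparisons on 1000 short series, permutation
calibration on 500 series × 79 shuffles, state recovery on 200 recordings,
model recovery on cohorts of 100 over 20 master seeds.

## Degenerate inputs and numerical conventions

Constant series give AMP 0, pNN5 0 and missing skewness (zero variance,
with a reason code); all-artifact input raises "no valid beats"; zero
analyzable minutes make STV/LTV missing with a reason rather than an
error; an LF band with zero power makes the ratio missing. Quantiles are
type 7 (linear interpolation) except the equiprobable bin edges (type 1,
exact order statistics). Epoch counts use `floor(duration / 3.75)` with a
1 ns guard against accumulated floating-point error in beat times.

## Limitations

The Dawes-Redman baseline and episode rules are reconstructions of
unpublished algorithms — tagged, configurable, and not claimed to
reproduce the commercial system. The state classifier approximates an
expert consensus with written rules only. The packaged LTV reference table
is synthetic. Below 26 completed weeks the normality criteria are not
defined and the package refuses to apply them.
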