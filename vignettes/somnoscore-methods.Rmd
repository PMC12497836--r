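---
title: "Quantifying rodent sleep and its pharmacological modulation with somnoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rodent sleep and its pharmacological modulation with somnoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscore)
```

## The measurement problem

Preclinical sleep pharmacology scores telemetric EEG/EMG into a hypnogram:
one label per 10-second epoch, over `WAKE`, `NREM`, `REM`, and `ARTIFACT`,
anchored to Zeitgeber time (ZT; hours since light onset in a 12:12
light/dark cycle). From that label sequence and the underlying signal, a
small set of quantities carries essentially all of the pharmacology:

* **state durations** summed in ZT bins (typically the cumulative 1, 3 and
  6 h after dosing),
* **sleep latencies** — time from dosing to the first NREM bout of at least
  30 s, or the first REM bout of at least 20 s,
* **continuity metrics** — bout counts and mean bout durations over the
  first 3 h, and **brief arousals** (waking runs of 20–30 s flanked by NREM
  on both sides), an index of fragmentation,
* **state-conditioned qEEG** — relative spectral power in conventional
  bands, expressed per animal as percent change from a pre-dosing baseline
  window.

somnoscore implements each of these as a small, separately testable
function, plus the repeated-measures statistics used in within-subject
crossover designs, and a synthetic generator so the whole pipeline can be
validated end to end without animal data.

## Hypnogram metrics

All epoch arithmetic is integer. A *bout* is a maximal run of identical
labels; anything else — including artifact — terminates the run
(`segment_bouts()`). Durations (`state_durations()`) assign each epoch to
the ZT bin containing its start, so the four state durations always sum
exactly to the binned time; artifact time is reported separately rather
than redistributed.

`sleep_latency()` snaps the dosing time forward to the next epoch boundary
(the epoch is the atomic unit of scoring) and scans for the first
qualifying bout. When none exists the remaining recording time is returned
with a `censored` flag; censored values are never imputed, and downstream
code decides explicitly how to treat them.

Two readings of "a brief arousal in the middle of a NREM bout" are
possible: the arousal interrupts the bout, or the bout continues across
it. The package treats bouts as pure maximal runs by default (the arousal
terminates the bout), which keeps segmentation a one-pass run-length
operation; the alternative is available as
`scoring_rules(arousal_tolerant_bouts = TRUE)`, in which case NREM runs
separated by exactly one qualifying arousal merge and the merged duration
counts sleep epochs only. The brief-arousal range is inclusive at both
ends: 20–30 s means 2 or 3 ten-second epochs.

## Spectral analysis

`epoch_psd()` computes a Welch estimate per epoch: Hamming-windowed
segments at 50% overlap, periodograms normalized by the window power and
sampling rate (so a unit-variance white signal is flat and its 0.5–100 Hz
total equals the variance in that span), averaged within the epoch, then
aggregated into 1-Hz bins.

Numerical choices worth stating:

* **Segment length defaults to 4 s** (0.25 Hz native resolution). The band
  edges sit on multiples of 0.5 Hz, so the native grid must resolve them;
  4-s segments additionally put every integer-frequency tone on an exact
  native bin with its window leakage confined inside one 1-Hz output bin.
  The segment length is a `spectral_config()` parameter.
* **1-Hz bin k covers [k − 0.5, k + 0.5) Hz**, tiling the half-open span
  [0.5, 100); the last bin is truncated at 100 Hz. Native bins are mapped
  by the same half-open rule, so bin contents and bin intervals agree
  exactly.
* **Band aggregation weights each bin by interval overlap.** A 1-Hz bin
  straddling a band edge contributes proportionally. Consequently a
  spectrally uniform epoch gives delta = 3.5/99.5 (the width of [0.5, 4)
  over the width of the span), and the non-overlapping bands plus the
  24–30 Hz remainder reconcile to exactly 1. The 24–30 Hz gap between beta
  and low gamma is preserved as conventionally printed, never silently
  merged; its power stays in the relative-power denominator.
* **Relative power** divides by the epoch's 0.5–100 Hz total. Zero-total or
  non-finite epochs propagate as missing — never zero-filled — and epochs
  containing non-finite samples are marked missing and logged.

`state_band_timecourse()` averages per-epoch band fractions within each
(ZT bin × state) cell, excluding artifact; `baseline_normalize()` then
expresses each subject's series as percent change from the epoch-weighted
mean over the baseline window (ZT 0–2 by default; designs that dose at ZT1
use ZT 0–1). Group averaging of fractions happens before normalization
within a subject, and across subjects only after each animal is normalized
to itself.

## Dose–response statistics

The designs are within-subject crossovers, so the module implements the
paired family: `paired_t()`, `linear_regression()` (reporting R², and
F = (n − 2)R²/(1 − R²) with df (1, n − 2), the identity that links the
columns of published correlation tables), `rm_anova_oneway()` (classical
one-way repeated-measures F with Greenhouse–Geisser epsilon from the
contrast covariance, both df scaled by epsilon), and
`dunnett_many_to_one()`.

The Dunnett adjustment is Monte Carlo: paired-difference t statistics
against the control, referred to the null distribution of the maximum
absolute statistic over the family, simulated (10^5 replicates by default,
seed recorded in the output) under the correlation estimated from the
observed difference scores with a shared chi-square scale at the smallest
comparison df. Adjusted p-values are floored at the raw paired-t p, so a
family of one reproduces the paired t exactly and monotonicity in the
family size holds. The test suite cross-checks the Monte Carlo tail
against an independent multivariate-t computation.

Published mixed-effects ANOVAs with fractional denominator df come from
proprietary software whose estimator is unstated; this module makes no
claim of numeric identity with such fits. It provides the classical
RM-ANOVA analogue with complete-case subjects (pairwise-complete for
Dunnett), stated openly, and emits tidy tables for anything beyond the
one-way case.

## The synthetic generator

`simulate_hypnogram()` draws a semi-Markov chain: exponential bout
durations (rounded to whole epochs, minimum one) with light/dark phase
means, a transition propensity matrix in which REM is enterable only from
NREM, and independent artifact overwriting. Exponential durations are the
simplest family consistent with run-length bout analysis; the long-run
occupancy has the closed form pi_i mu_i / sum(pi_j mu_j), which
`stationary_occupancy()` evaluates (including the epoch-rounding
correction) and the test suite verifies against a 10^6-epoch simulation.

Defaults are literature-typical for adult rats — light phase: mean bouts
150 s wake / 300 s NREM / 100 s REM (about 29/63/7% occupancy); dark
phase: 600/180/80 s. No baseline architecture numbers are claimed for any
particular study; these are configuration, and every validation exercise
runs under them. The default artifact rate is 0.2% of epochs, a
clean-recording figure chosen because random artifact epochs truncate
run-length bouts: at rate q the observed mean of a mu-epoch bout shrinks
to roughly 1/(1/mu + q), about 5% at 0.2% but over 20% at 1%. Parameter
recovery therefore reads back the configured bout mean only when artifact
is rare, which is the regime the metrics themselves assume.

Interventions are multiplicative and time-limited
(`intervention_effect()`). One deliberate modeling decision: the *wake
propensity* multiplier scales both the transition weights into WAKE and
the WAKE mean bout duration. With WAKE → NREM the only exit from wake,
transition weights alone could neither lengthen waking (a noxious
stimulus) nor shorten sleep latency (a sedative); a single wake-drive
multiplier reproduces both phenotypes. Dosing itself matters: every
injection, vehicle included, forces a *handling arousal* — a waking bout
drawn from a gamma distribution (shape 4) whose mean (8 min by default) is
scaled by the compound's wake-drive multiplier — so latencies behave the
way handled animals' latencies do. The shipped presets encode the study
phenotypes qualitatively: a lactic-acid-like transient (1.5 h) wake
promotion with NREM/REM suppression, a morphine-like suppression with an
added dose-scaled latency delay, an NSAID null, and an AT-403-like 6-h
NREM promotion with REM suppression.

`synthesize_eeg()` shapes white Gaussian noise in the frequency domain to
state-typical band templates over a 1/f background (delta-dominant NREM
with a sigma contribution, theta-dominant REM, broadband wake), cross-fading
epochs over 0.1 s with complementary square-root ramps so splices add no
step artifacts. It makes no attempt at waveform morphology — no spindles,
K-complexes, or phase structure — so passing spectral round-trips validate
the *pipeline*, not biological realism.

`simulate_cohort()` assembles the crossover: cyclic Latin-square condition
order, at least 3 days of washout, and a per-animal-session severity
latent (SD 1.5) that scales stretching counts up while intensifying the
noxious stimulus's wake promotion, making stretching and NREM duration
inversely coupled across animals. Behavior counts are Poisson with
log-linear concentration terms. The coupling strength was calibrated once
so that the stretching-versus-NREM regression at n = 7 under the
5.6% condition has its R² distribution centered near 0.66 with
interquartile range about [0.57, 0.79] — i.e. population strength around
0.7 — and then frozen. A corollary worth knowing: that same severity
variance makes single-concentration group comparisons of the noxious
stimulus noisier than the preset-only simulations, which is one reason the
behavioral regression and the group ANOVA answer different questions.

## Problem sizes used in validation

The shipped validation suites run at deliberately modest sizes chosen as
adequate for their tolerances: 1,000 random 500-epoch hypnograms against
brute-force oracles; 200 ten-second epochs of white noise for spectral
flatness (about 2.3% across-bin coefficient of variation — with this much
averaging the per-bin chi-square noise, not the estimator, limits
flatness); 200 simulated animals for parameter recovery (10% tolerance);
15 paired animals per intervention phenotype; 1,000 null datasets for the
Dunnett family-wise error (nominal 0.05, accepted within [0.035, 0.065]);
10^5 Monte Carlo replicates per Dunnett call.

## Known limitations

* Bout durations are memoryless; real rodent bout distributions are
  heavier-tailed (log-normal/gamma survival is commonly reported).
* Circadian structure is a two-phase switch, not continuous modulation.
* The severity latent is a single scalar per animal-session; it does not
  model sex differences (beyond what a user encodes in parameters) or
  tolerance across sessions.
* Automated sleep scoring is out of scope: labels are inputs, and the
  generator's ground truth stands in for a human scorer.
* The EDF layer covers 16-bit single-rate signals, not EDF+ annotations.
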