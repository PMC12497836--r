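# somnoscore

Sleep architecture and quantitative EEG analysis for rodent dose–response
studies.

Preclinical studies of analgesics and sleep score telemetric EEG into a
hypnogram — one label per 10-s epoch over wake / NREM sleep / REM sleep /
artifact, anchored to Zeitgeber time (ZT, hours since light onset) — and
then ask a standard set of questions: how much time in each state per 1/3/6-h
bin after dosing; how long until the first qualifying NREM (≥ 30 s) or REM
(≥ 20 s) bout; how fragmented is sleep (bout counts, mean bout durations,
brief arousals of 20–30 s flanked by NREM); and how does state-conditioned
spectral power (delta 0.5–4 Hz, theta 4–8, alpha 8–12, sigma 12–16, beta
16–24, low/high gamma 30–50/50–100) change relative to each animal's own
pre-dosing baseline. Dose effects in within-subject crossover designs are
tested with paired *t*-tests, one-way repeated-measures ANOVA with
Greenhouse–Geisser correction, Dunnett many-to-one comparisons against
vehicle, and within-subject linear regressions (R², F = (n−2)R²/(1−R²)).

somnoscore implements that entire pipeline as small, separately tested
functions:

* **I/O** — EDF signal read/write, strict delimited readers for hypnograms,
  dosing events, behavior counts; deterministic TSV output
  (`read_edf()`, `read_hypnogram()`, `write_metrics_table()`, …)
* **Hypnogram metrics** — `segment_bouts()`, `state_durations()`,
  `sleep_latency()`, `count_brief_arousals()`, `bout_statistics()`,
  `sleep_metrics()`
* **qEEG** — per-epoch Welch PSD in 1-Hz bins 0.5–100 Hz (Hamming window,
  50% overlap), relative band power, state-conditioned time courses,
  baseline normalization (`epoch_psd()`, `band_power()`,
  `state_band_timecourse()`, `baseline_normalize()`)
* **Statistics** — `paired_t()`, `linear_regression()`,
  `rm_anova_oneway()`, `dunnett_many_to_one()` (Monte Carlo max-|t|
  family-wise adjustment)
* **Synthetic data** — a semi-Markov sleep simulator with intervention
  presets (noxious visceral stimulus, mu-opioid, NSAID, NOP agonist),
  a spectrally shaped surrogate-EEG synthesizer, and a Poisson behavior
  model with a severity latent coupling pain behavior to sleep loss
  (`simulate_hypnogram()`, `synthesize_eeg()`, `simulate_cohort()`)
* **Pipeline** — `run_pipeline()` orchestrates simulate/ingest → metrics →
  qEEG → statistics with a JSON manifest; `exec/somnoscore` is a thin CLI.

See `vignettes/somnoscore-methods.Rmd` for the models, conventions and
numerical choices.

## Worked example

Simulate a morphine crossover (n = 8, vehicle/1/3/10 mg/kg i.p. at ZT2,
counterbalanced), compute NREM minutes over the 3 h post-dosing, and test
the dose effect:

```r
library(somnoscore)

des <- experiment_design(n_subjects = 8, compound = "morphine",
                         doses = c(0, 1, 3, 10), dosing_zt = 2, hours = 8)
coh <- simulate_cohort(des, seed = 42)

m <- do.call(rbind, lapply(coh$sessions, function(s)
  sleep_metrics(s$hypnogram, t0_zt = 2, bins_h = 3,
                subject_id = s$subject_id, condition = s$condition)))
summarize_timecourse(m, "nrem_min")
#>     condition bin_end  mean n  sem
#> 2  morphine_1       5  91.6 8 5.91
#> 4 morphine_10       5  14.3 8 5.65
#> 3  morphine_3       5  56.5 8 4.86
#> 1     vehicle       5 108.5 8 3.39

Y <- with(m, tapply(nrem_min, list(subject_id, condition), mean))
Y <- Y[, c("vehicle", "morphine_1", "morphine_3", "morphine_10")]
rm_anova_oneway(rm_design(Y, control = "vehicle"), dunnett = TRUE, seed = 1)
#> One-way RM-ANOVA: F(2.019, 14.13) = 76.51, p = 2.525e-08 (GG epsilon = 0.673, n = 8)
#> Dunnett vs vehicle
#>     condition estimate       t df     p_raw     p_adj
#> 1  morphine_1   -16.90  -2.116  7 7.214e-02 1.613e-01
#> 2  morphine_3   -52.00 -10.191  7 1.888e-05 3.000e-05
#> 3 morphine_10   -94.27 -18.509  7 3.333e-07 3.333e-07
```

Vehicle animals sleep about 108 of the 180 minutes; morphine suppresses
NREM dose-dependently (to 14 min at 10 mg/kg), the repeated-measures F is
sphericity-corrected (epsilon 0.67), and Dunnett flags 3 and 10 mg/kg
against vehicle while 1 mg/kg does not separate.

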