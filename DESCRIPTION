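Package: somnoscore
Title: Sleep Architecture and Quantitative EEG Analysis for Rodent
    Dose-Response Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies rodent sleep from epoch-scored hypnograms and
    continuous EEG: state durations in Zeitgeber-time bins, NREM/REM sleep
    latencies, bout segmentation and fragmentation metrics (brief arousals),
    Welch power spectral density in 1-Hz bins with relative band power and
    within-subject baseline normalization, and the repeated-measures
    dose-response statistics used in crossover designs (paired t, simple
    linear regression, one-way RM-ANOVA with Greenhouse-Geisser correction,
    and Dunnett many-to-one comparisons). Includes a semi-Markov sleep
    simulator and surrogate EEG synthesizer with intervention presets
    (visceral noxious stimulus, mu-opioid, NSAID, NOP agonist) so every
    pipeline stage can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
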