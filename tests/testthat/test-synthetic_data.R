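test_that("the simulator is deterministic and respects hard constraints", {
  p <- sleep_architecture_params()
  h1 <- simulate_hypnogram(p, hours = 24, seed = 42)
  h2 <- simulate_hypnogram(p, hours = 24, seed = 42)
  expect_identical(h1$labels, h2$labels)
  expect_length(h1$labels, 8640)

  # zero REM propensity: no REM anywhere
  p0 <- sleep_architecture_params(
    propensity = matrix(c(0, 1, 0, 1, 0, 0, 0.8, 0.2, 0), 3, byrow = TRUE,
                        dimnames = list(c("WAKE", "NREM", "REM"),
                                        c("WAKE", "NREM", "REM"))))
  h0 <- simulate_hypnogram(p0, hours = 12, seed = 9)
  expect_false("REM" %in% h0$labels)

  # REM only after NREM (modulo artifact masking)
  pa <- sleep_architecture_params(artifact_rate = 0)
  hr <- simulate_hypnogram(pa, hours = 24, seed = 3)
  runs <- rle(hr$labels)$values
  before_rem <- runs[which(runs == "REM") - 1L]
  expect_true(all(before_rem == "NREM"))
})

test_that("invalid architecture parameters are rejected", {
  expect_error(sleep_architecture_params(artifact_rate = 0.2), "0.05")
  bad <- matrix(c(0, 0.5, 0.5, 1, 0, 0, 1, 0, 0), 3, byrow = TRUE,
                dimnames = list(c("WAKE", "NREM", "REM"),
                                c("WAKE", "NREM", "REM")))
  expect_error(sleep_architecture_params(propensity = bad),
               "REM is enterable only from NREM")
})

test_that("long-run occupancy converges to the analytic stationary value", {
  m <- c(WAKE = 150, NREM = 300, REM = 100)
  p <- sleep_architecture_params(mean_bout_s = list(light = m, dark = m),
                                 artifact_rate = 0)
  h <- simulate_hypnogram(p, hours = 1e6 / 360, seed = 5)   # 1e6 epochs
  occ <- prop.table(table(factor(h$labels, c("WAKE", "NREM", "REM"))))
  an <- stationary_occupancy(p, "light")
  expect_equal(as.numeric(occ), as.numeric(an), tolerance = 0.02)
})

test_that("surrogate EEG recovers the template band fractions", {
  tpl <- spectral_template(templates = list(
    WAKE = c(delta = 0.2, theta = 0.2, alpha = 0.1, sigma = 0.1,
             beta = 0.1, low_gamma = 0.15, high_gamma = 0.1),
    NREM = c(delta = 0.6, theta = 0.1, alpha = 0.05, sigma = 0.1,
             beta = 0.05, low_gamma = 0.04, high_gamma = 0.03),
    REM = c(delta = 0.1, theta = 0.5, alpha = 0.1, sigma = 0.05,
            beta = 0.1, low_gamma = 0.08, high_gamma = 0.04)))
  hn <- hypnogram(rep("NREM", 60))
  rec <- synthesize_eeg(hn, tpl, sampling_rate = 250, seed = 4)
  bp <- band_power(relative_power(epoch_psd(rec, hn)))
  expect_lt(abs(mean(bp[, "delta"]) - 0.6), 0.05)

  # identical seeds give identical sample streams
  rec2 <- synthesize_eeg(hn, tpl, sampling_rate = 250, seed = 4)
  expect_identical(rec$samples, rec2$samples)

  # state ordering: delta(NREM) > delta(REM), theta(REM) > theta(NREM)
  hr <- hypnogram(rep("REM", 60))
  rr <- synthesize_eeg(hr, tpl, sampling_rate = 250, seed = 5)
  bpr <- band_power(relative_power(epoch_psd(rr, hr)))
  expect_gt(mean(bp[, "delta"]), mean(bpr[, "delta"]))
  expect_gt(mean(bpr[, "theta"]), mean(bp[, "theta"]))
})

test_that("interventions are local: outside the window vehicle and treated match", {
  p <- sleep_architecture_params()
  n <- 40
  veh <- trt <- numeric(n)
  for (i in seq_len(n)) {
    hv <- simulate_hypnogram(p, intervention_preset("lactic_acid", 0),
                             hours = 12, seed = 9000 + i)
    ht <- simulate_hypnogram(p, intervention_preset("lactic_acid", 5.6),
                             hours = 12, seed = 9500 + i)
    veh[i] <- state_durations(hv, c(8, 12))$nrem_min
    trt[i] <- state_durations(ht, c(8, 12))$nrem_min
  }
  expect_gt(t.test(veh, trt)$p.value, 0.01)
})

test_that("cohort simulation counterbalances and links severity to sleep and behavior", {
  des <- experiment_design(8, "lactic_acid", doses = c(0, 1.8, 5.6),
                           dosing_zt = 2, hours = 4)
  coh <- simulate_cohort(des, seed = 21)
  expect_equal(nrow(coh$events), 24)
  expect_equal(sort(unique(coh$events$condition)),
               sort(c("vehicle", "lactic_acid_1.8", "lactic_acid_5.6")))
  # Latin-square: every condition appears in every session position
  tab <- table(coh$events$condition, coh$events$session)
  expect_true(all(tab > 0))

  # concentration-dependent behavior: stretching up, rearing down at 5.6%
  b <- coh$behavior
  expect_gt(mean(b$stretching[b$condition == "lactic_acid_5.6"]),
            mean(b$stretching[b$condition == "vehicle"]))
  expect_lt(mean(b$rearing[b$condition == "lactic_acid_5.6"]),
            mean(b$rearing[b$condition == "vehicle"]))

  expect_error(experiment_design(4, "morphine", doses = c(0, 1, 3),
                                 latin_square = matrix(1:4, 2)),
               "Latin square")
  expect_error(experiment_design(4, "morphine", doses = c(0, 1),
                                 washout_days = 1), "washout")
})

test_that("null severity coupling removes the stretching-sleep correlation", {
  bm0 <- behavior_model(severity_behavior = 0, severity_sleep = 0)
  r2 <- numeric(40)
  for (c in seq_len(40)) {
    des <- experiment_design(7, "lactic_acid", doses = 5.6, dosing_zt = 2,
                             hours = 3)
    coh <- simulate_cohort(des, bmodel = bm0, seed = 14000 + c * 37)
    nrem <- vapply(coh$sessions, function(s)
      state_durations(s$hypnogram, c(2, 3))$nrem_min, numeric(1))
    str <- coh$behavior$stretching[match(
      names(coh$sessions),
      paste(coh$behavior$subject_id, coh$behavior$condition, sep = "_"))]
    r2[c] <- linear_regression(str, nrem)$r_squared
  }
  expect_lte(mean(r2), 0.25)
})

test_that("default coupling yields a dose-response regression near the reference strength", {
  r2 <- numeric(40)
  for (c in seq_len(40)) {
    des <- experiment_design(7, "lactic_acid", doses = 5.6, dosing_zt = 2,
                             hours = 3)
    coh <- simulate_cohort(des, seed = 15000 + c * 37)
    nrem <- vapply(coh$sessions, function(s)
      state_durations(s$hypnogram, c(2, 3))$nrem_min, numeric(1))
    str <- coh$behavior$stretching[match(
      names(coh$sessions),
      paste(coh$behavior$subject_id, coh$behavior$condition, sep = "_"))]
    r2[c] <- linear_regression(str, nrem)$r_squared
  }
  expect_gte(quantile(r2, 0.75), 0.7022)
  expect_lte(quantile(r2, 0.25), 0.7022)
})

test_that("preset YAML files load into valid interventions", {
  dir <- system.file("extdata", "presets", package = "somnoscore")
  for (f in list.files(dir, full.names = TRUE)) {
    iv <- read_intervention(f)
    expect_s3_class(iv[[1L]], "intervention_effect")
  }
  la <- read_intervention(file.path(dir, "lactic_acid_5p6.yaml"))[[1L]]
  code <- intervention_preset("lactic_acid", 5.6)[[1L]]
  expect_equal(la$wake_propensity_mult, code$wake_propensity_mult,
               tolerance = 1e-3)
})
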