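tone_rec <- function(f0, fs = 500, n_epochs = 1, amp = 1) {
  t <- 0:(n_epochs * 10 * fs - 1) / fs
  eeg_recording(amp * sin(2 * pi * f0 * t), fs)
}

test_that("a pure tone concentrates in its 1-Hz bin with the argmax at f", {
  h <- hypnogram("WAKE")
  for (f0 in c(2, 6, 10, 20, 40, 80)) {
    rel <- relative_power(epoch_psd(tone_rec(f0), h))
    expect_equal(which.max(rel), f0)
    expect_gte(rel[f0], 0.99)
  }
})

test_that("zero and missing epochs propagate correctly", {
  h <- hypnogram(rep("WAKE", 3))
  fs <- 250
  x <- c(numeric(10 * fs), rnorm(10 * fs), rnorm(10 * fs))
  x[2.5 * 10 * fs] <- NaN
  rec <- eeg_recording(x, fs, allow_missing = TRUE)
  psd <- suppressMessages(epoch_psd(rec, h))
  expect_equal(unname(psd$power[1L, ]), numeric(100))
  expect_true(all(is.na(psd$power[3L, ])))
  expect_false(anyNA(psd$power[2L, ]))

  rel <- relative_power(psd)
  expect_true(all(is.na(rel[1L, ])))     # zero-total row is missing, not zero
})

test_that("signal and hypnogram may differ by at most one epoch", {
  fs <- 250
  h <- hypnogram(rep("WAKE", 4))
  expect_error(epoch_psd(eeg_recording(rnorm(2 * 10 * fs), fs), h),
               "more than one epoch")
  psd <- suppressMessages(epoch_psd(eeg_recording(rnorm(3 * 10 * fs), fs), h))
  expect_equal(nrow(psd$power), 4L)
  expect_true(all(is.na(psd$power[4L, ])))
})

test_that("relative power rows are normalized and scale-invariant", {
  set.seed(31)
  p <- matrix(rexp(5 * 100), 5)
  rel <- relative_power(p)
  expect_equal(rowSums(rel), rep(1, 5), tolerance = 1e-9)
  expect_equal(relative_power(7.3 * p), rel)

  one <- numeric(100); one[42] <- 3.3
  expect_equal(relative_power(one)[42], 1)
  expect_equal(sum(relative_power(one)[-42]), 0)
})

test_that("band power follows bin-interval overlap and reconciles totals", {
  # uniform density across the span: band fraction = band width / span width
  bins <- rep(1, 100); bins[100] <- 0.5
  rel <- relative_power(bins)
  bp <- band_power(rel)
  expect_equal(unname(bp["delta"]), 3.5 / 99.5, tolerance = 1e-12)
  expect_equal(unname(bp["theta"]), 4 / 99.5, tolerance = 1e-12)
  expect_equal(unname(bp["total_gamma"]),
               unname(bp["low_gamma"] + bp["high_gamma"]), tolerance = 1e-12)

  # non-overlapping bands + the 24-30 Hz remainder tile the span
  named <- bp[c("delta", "theta", "alpha", "sigma", "beta", "low_gamma",
                "high_gamma")]
  remainder <- band_power(rel, band_scheme(gap = c(24, 30)))
  expect_equal(sum(named) + unname(remainder["gap"]), 1, tolerance = 1e-9)

  expect_error(band_scheme(ultra = c(90, 140)), "outside the 0.5-100 Hz span")
})

test_that("tones land in the conventional bands", {
  h <- hypnogram("WAKE")
  bp2 <- band_power(relative_power(epoch_psd(tone_rec(2), h)))
  expect_gte(bp2[, "delta"], 0.99)
  bp6 <- band_power(relative_power(epoch_psd(tone_rec(6), h)))
  expect_gte(bp6[, "theta"], 0.95)
  expect_lte(bp6[, "delta"] + bp6[, "alpha"], 0.05)
  # moving the tone from 6 to 10 Hz moves its dominant band theta -> alpha
  bp10 <- band_power(relative_power(epoch_psd(tone_rec(10), h)))
  expect_gt(bp6[, "theta"], bp6[, "alpha"])
  expect_gt(bp10[, "alpha"], bp10[, "theta"])
})

test_that("white-noise spectra are flat and match the variance oracle", {
  fs <- 500
  set.seed(99)
  n_ep <- 60
  x <- rnorm(n_ep * 10 * fs)
  psd <- epoch_psd(eeg_recording(x, fs), hypnogram(rep("WAKE", n_ep)))
  dens <- colMeans(psd$power) / (psd$bin_upper - psd$bin_lower)
  expect_lte(sd(dens) / mean(dens), 0.05)
  tot <- mean(rowSums(psd$power))
  oracle <- var(x) * sum(psd$bin_upper - psd$bin_lower) / (fs / 2)
  expect_lt(abs(tot / oracle - 1), 0.1)
})

test_that("amplitude scaling leaves relative power and percent change unchanged", {
  fs <- 250
  set.seed(5)
  n_ep <- 12
  h <- hypnogram(rep(c("WAKE", "NREM"), n_ep / 2))
  x <- rnorm(n_ep * 10 * fs)
  p1 <- epoch_psd(eeg_recording(x, fs), h)
  p2 <- epoch_psd(eeg_recording(2 * x, fs), h)
  expect_equal(relative_power(p2), relative_power(p1), tolerance = 1e-12)

  edges <- seq(0, n_ep / 360, length.out = 3)
  tc1 <- suppressMessages(
    baseline_normalize(state_band_timecourse(p1, h, bin_edges_zt = edges),
                       baseline_window_zt = edges[1:2]))
  tc2 <- suppressMessages(
    baseline_normalize(state_band_timecourse(p2, h, bin_edges_zt = edges),
                       baseline_window_zt = edges[1:2]))
  expect_equal(tc2$pct_change, tc1$pct_change, tolerance = 1e-10)
})

test_that("state timecourse is a per-state group mean excluding artifact", {
  fs <- 250
  set.seed(8)
  n_ep <- 40
  labs <- sample(c("WAKE", "NREM", "REM", "ARTIFACT"), n_ep, replace = TRUE,
                 prob = c(.4, .4, .1, .1))
  labs[1:4] <- c("WAKE", "NREM", "REM", "ARTIFACT")  # every state present
  h <- hypnogram(labs)
  psd <- epoch_psd(eeg_recording(rnorm(n_ep * 10 * fs), fs), h)
  edges <- c(0, n_ep * 10 / 3600)
  tc <- state_band_timecourse(psd, h, bin_edges_zt = edges)

  bands <- band_power(relative_power(psd))
  for (st in c("WAKE", "NREM", "REM")) {
    want <- mean(bands[labs == st, "delta"])
    got <- tc$value[tc$state == st & tc$band == "delta"]
    expect_equal(got, want)
  }
  expect_false(any(tc$state == "ARTIFACT"))

  # a bin with no epochs of a state is missing
  h2 <- hypnogram(rep("WAKE", 6))
  psd2 <- epoch_psd(eeg_recording(rnorm(6 * 10 * fs), fs), h2)
  tc2 <- state_band_timecourse(psd2, h2, bin_edges_zt = c(0, 1 / 60))
  expect_true(all(is.na(tc2$value[tc2$state == "REM"])))

  # permutation within the bin-state group leaves the mean unchanged
  perm <- sample(which(labs == "WAKE"))
  psd_p <- psd
  psd_p$power[which(labs == "WAKE"), ] <- psd$power[perm, ]
  tc_p <- state_band_timecourse(psd_p, h, bin_edges_zt = edges)
  expect_equal(tc_p$value[tc_p$state == "WAKE"],
               tc$value[tc$state == "WAKE"], tolerance = 1e-12)
})

test_that("baseline normalization is exact percent change from the window", {
  tc <- data.frame(subject_id = "r1",
                   state = "WAKE", band = "delta",
                   bin_start = c(0, 1, 2, 3), bin_end = c(1, 2, 3, 4),
                   value = c(0.2, 0.2, 0.4, 0.1), n_epochs = c(10, 10, 10, 10))
  out <- baseline_normalize(tc, c(0, 2))
  expect_equal(out$pct_change, c(0, 0, 100, -50))

  # missing baseline propagates NA, never zero
  tc$value[1:2] <- NA
  out2 <- suppressMessages(baseline_normalize(tc, c(0, 2)))
  expect_true(all(is.na(out2$pct_change)))

  # group mean of per-subject percent change equals the two-step computation
  set.seed(12)
  tcs <- do.call(rbind, lapply(sprintf("r%d", 1:5), function(sid) {
    v <- runif(4, 0.1, 0.5)
    data.frame(subject_id = sid, state = "NREM", band = "delta",
               bin_start = 0:3, bin_end = 1:4, value = v, n_epochs = 10)
  }))
  out3 <- baseline_normalize(tcs, c(0, 1))
  grp <- tapply(out3$pct_change[out3$bin_start == 3],
                out3$subject_id[out3$bin_start == 3], mean)
  manual <- vapply(sprintf("r%d", 1:5), function(sid) {
    v <- tcs$value[tcs$subject_id == sid]
    100 * (v[4] - v[1]) / v[1]
  }, numeric(1))
  expect_equal(mean(grp), mean(manual))
})
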