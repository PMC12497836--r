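test_that("segment_bouts finds maximal runs terminated by any other label", {
  h <- hypnogram(c("NREM", "NREM", "NREM", "WAKE", "NREM"))
  b <- segment_bouts(h, "NREM")
  expect_equal(b$start_s, c(0, 40))
  expect_equal(b$duration_s, c(30, 10))

  expect_equal(nrow(segment_bouts(hypnogram(rep("WAKE", 100)), "NREM")), 0L)

  # artifact splits a run just like any other label
  ha <- hypnogram(c("NREM", "NREM", "ARTIFACT", "NREM"))
  expect_equal(segment_bouts(ha, "NREM")$duration_s, c(20, 10))

  expect_error(segment_bouts(h, "DROWSY"), "unknown state")
})

test_that("bout segmentation matches a brute-force scan on random hypnograms", {
  for (s in 1:60) {
    h <- random_hypnogram(500, seed = 1000 + s)
    for (state in c("WAKE", "NREM", "REM")) {
      got <- segment_bouts(h, state)
      want <- oracle_bouts(h$labels, state)
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$duration_s, want$duration_s)
    }
  }
})

test_that("bouts partition the state's epochs", {
  for (s in 1:10) {
    h <- random_hypnogram(400, seed = 50 + s)
    total_h <- length(h$labels) * h$epoch_length / 3600
    sd <- state_durations(h, c(0, total_h))
    for (state in c("NREM", "REM")) {
      b <- segment_bouts(h, state)
      col <- paste0(tolower(state), "_min")
      expect_equal(sum(b$duration_s) / 60, sd[[col]])
    }
  }
})

test_that("state durations conserve bin time and bin by epoch start", {
  h <- hypnogram(rep("NREM", 360))                  # 1 h
  sd <- state_durations(h, c(0, 1))
  expect_equal(sd$nrem_min, 60)
  expect_equal(sd$wake_min + sd$rem_min + sd$artifact_min, 0)

  h2 <- hypnogram(rep(c("WAKE", "NREM"), 540))      # 3 h alternating
  sd2 <- state_durations(h2, c(0, 3))
  expect_equal(sd2$wake_min, 90)
  expect_equal(sd2$nrem_min, 90)

  for (s in 1:10) {
    h3 <- random_hypnogram(720, seed = 200 + s)
    edges <- c(0, 0.5, 1, 2)
    sd3 <- state_durations(h3, edges)
    expect_equal(sd3$wake_min + sd3$nrem_min + sd3$rem_min + sd3$artifact_min,
                 diff(edges) * 60)
  }

  expect_error(state_durations(h, c(0, 2)), "outside the recording")
})

test_that("sleep latency honors the minimum-bout rule", {
  # two NREM epochs (20 s) do not qualify; the 3-epoch run at epoch 5 does
  h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "WAKE",
                   "NREM", "NREM", "NREM", "WAKE", "WAKE"))
  lat <- sleep_latency(h, "NREM", 0)
  expect_false(lat$censored)
  expect_equal(lat$latency_min, 50 / 60)

  # the same two-epoch run does qualify for REM's 20-s minimum
  hr <- hypnogram(c("WAKE", "WAKE", "REM", "REM", "WAKE"))
  expect_equal(sleep_latency(hr, "REM", 0)$latency_min, 20 / 60)

  cen <- sleep_latency(hypnogram(rep("WAKE", 30)), "REM", 0)
  expect_true(cen$censored)
  expect_equal(cen$latency_min, 5)

  expect_error(sleep_latency(h, "NREM", 10), "outside the recording")
})

test_that("latency matches a brute-force scan and is monotone in threshold", {
  rules30 <- scoring_rules()
  for (s in 1:60) {
    h <- random_hypnogram(500, seed = 3000 + s)
    t0_ep <- sample(0:400, 1)
    t0_zt <- t0_ep * 10 / 3600
    got <- sleep_latency(h, "NREM", t0_zt, rules30)
    want <- oracle_latency(h$labels, "NREM", t0_ep, 30)
    expect_equal(got$latency_min, want$latency_min)
    expect_equal(got$censored, want$censored)

    gotr <- sleep_latency(h, "REM", t0_zt, rules30)
    wantr <- oracle_latency(h$labels, "REM", t0_ep, 20)
    expect_equal(gotr$latency_min, wantr$latency_min)

    # a stricter minimum can only delay (or censor) the latency
    strict <- scoring_rules(nrem_latency_min_bout_s = 60)
    expect_gte(sleep_latency(h, "NREM", t0_zt, strict)$latency_min,
               got$latency_min)
  }
})

test_that("brief arousals need 20-30 s of wake flanked by NREM", {
  expect_equal(count_brief_arousals(
    hypnogram(c("NREM", "NREM", "WAKE", "WAKE", "NREM", "NREM"))), 1L)
  # 40 s exceeds the inclusive upper bound
  expect_equal(count_brief_arousals(
    hypnogram(c("NREM", "NREM", "WAKE", "WAKE", "WAKE", "WAKE", "NREM"))), 0L)
  # 30 s is still inside the inclusive range
  expect_equal(count_brief_arousals(
    hypnogram(c("NREM", "WAKE", "WAKE", "WAKE", "NREM"))), 1L)
  # recording edge: not flanked on both sides
  expect_equal(count_brief_arousals(
    hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "WAKE", "WAKE"))), 0L)
  # REM flanking does not count
  expect_equal(count_brief_arousals(
    hypnogram(c("REM", "WAKE", "WAKE", "NREM", "NREM"))), 0L)
  # no NREM at all implies zero
  expect_equal(count_brief_arousals(
    hypnogram(rep(c("WAKE", "REM"), 20))), 0L)
})

test_that("brief arousal counts match the brute-force scan", {
  for (s in 1:60) {
    h <- random_hypnogram(500, seed = 7000 + s,
                          probs = c(WAKE = 0.3, NREM = 0.55, REM = 0.1,
                                    ARTIFACT = 0.05))
    expect_equal(count_brief_arousals(h), oracle_brief_arousals(h$labels))
    # never more than the number of wake runs
    runs <- rle(h$labels)
    expect_lte(count_brief_arousals(h), sum(runs$values == "WAKE"))
  }
})

test_that("bout statistics count window starts and never report mean 0", {
  b <- data.frame(start_s = c(0, 100), duration_s = c(30, 90))
  st <- bout_statistics(b)
  expect_equal(st$count, 2L)
  expect_equal(st$mean_duration_s, 60)

  st0 <- bout_statistics(b[0L, ])
  expect_equal(st0$count, 0L)
  expect_true(is.na(st0$mean_duration_s))

  # only bouts starting inside the window count
  stw <- bout_statistics(b, window_s = c(0, 100))
  expect_equal(stw$count, 1L)
})

test_that("metrics ignore artifact appended after the analysis window", {
  h <- random_hypnogram(360, seed = 77)
  h_ext <- hypnogram(c(h$labels, rep("ARTIFACT", 60)))
  expect_equal(state_durations(h, c(0, 0.5)), state_durations(h_ext, c(0, 0.5)))
  expect_equal(count_brief_arousals(h, c(0, 0.5)),
               count_brief_arousals(h_ext, c(0, 0.5)))
  expect_equal(sleep_latency(h, "NREM", 0)$latency_min,
               sleep_latency(h_ext, "NREM", 0)$latency_min)
})

test_that("arousal-tolerant segmentation bridges brief arousals only", {
  h <- hypnogram(c("NREM", "NREM", "WAKE", "WAKE", "NREM", "NREM",
                   "WAKE", "WAKE", "WAKE", "WAKE", "NREM"))
  strict <- segment_bouts(h, "NREM")
  expect_equal(nrow(strict), 3L)

  tol <- segment_bouts(h, "NREM",
                       scoring_rules(arousal_tolerant_bouts = TRUE))
  # the 20-s arousal is bridged (sleep epochs only); the 40-s wake is not
  expect_equal(nrow(tol), 2L)
  expect_equal(tol$duration_s[1L], 40)
})

test_that("sleep_metrics rows conserve time and repeat window metrics", {
  h <- random_hypnogram(8640, seed = 123)
  m <- sleep_metrics(h, t0_zt = 2, bins_h = c(1, 3, 6),
                     subject_id = "rat01", condition = "vehicle")
  expect_equal(nrow(m), 3L)
  expect_equal(m$wake_min + m$nrem_min + m$rem_min + m$artifact_min,
               (m$bin_end - m$bin_start) * 60)
  expect_equal(length(unique(m$nrem_latency_min)), 1L)
  expect_equal(length(unique(m$brief_arousals)), 1L)
})
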