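# Brute-force oracles for hypnogram metrics: plain epoch-by-epoch scans,
# deliberately independent of the run-length implementation under test.

random_hypnogram <- function(n, seed,
                             probs = c(WAKE = 0.35, NREM = 0.45, REM = 0.12,
                                       ARTIFACT = 0.08),
                             epoch_length = 10, start_zt = 0) {
  set.seed(seed)
  hypnogram(sample(names(probs), n, replace = TRUE, prob = probs),
            epoch_length = epoch_length, start_zt = start_zt)
}

# scan every epoch, opening/closing a bout of `state` as labels change
oracle_bouts <- function(labels, state, epoch_length = 10) {
  starts <- integer(0); lens <- integer(0)
  open <- FALSE
  for (i in seq_along(labels)) {
    if (labels[i] == state) {
      if (!open) {
        starts <- c(starts, i - 1L)
        lens <- c(lens, 0L)
        open <- TRUE
      }
      lens[length(lens)] <- lens[length(lens)] + 1L
    } else {
      open <- FALSE
    }
  }
  data.frame(start_s = starts * epoch_length,
             duration_s = lens * epoch_length)
}

# first bout of `state` with duration >= min_s starting at/after epoch t0_ep
oracle_latency <- function(labels, state, t0_ep, min_s, epoch_length = 10) {
  b <- oracle_bouts(labels, state, epoch_length)
  ok <- b$duration_s >= min_s & b$start_s >= t0_ep * epoch_length
  if (any(ok)) {
    list(latency_min = (min(b$start_s[ok]) - t0_ep * epoch_length) / 60,
         censored = FALSE)
  } else {
    list(latency_min = (length(labels) - t0_ep) * epoch_length / 60,
         censored = TRUE)
  }
}

# WAKE runs of 20-30 s (inclusive) with NREM immediately on both sides
oracle_brief_arousals <- function(labels, min_s = 20, max_s = 30,
                                  epoch_length = 10) {
  count <- 0L
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == "WAKE") {
      j <- i
      while (j < n && labels[j + 1L] == "WAKE") j <- j + 1L
      dur <- (j - i + 1L) * epoch_length
      if (dur >= min_s && dur <= max_s && i > 1L && j < n &&
          labels[i - 1L] == "NREM" && labels[j + 1L] == "NREM") {
        count <- count + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

# group-by mean via a plain loop, for timecourse/summary cross-checks
oracle_group_mean <- function(values, keys) {
  uk <- unique(keys)
  out <- numeric(length(uk))
  for (g in seq_along(uk)) out[g] <- mean(values[keys == uk[g]])
  names(out) <- uk
  out
}
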