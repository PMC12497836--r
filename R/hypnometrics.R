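# Hypnogram-derived sleep architecture metrics: bout segmentation, state
# durations in ZT bins, sleep latencies, brief arousals, bout statistics.
# All arithmetic is integer in epochs; durations convert at the end.

# run-length view of a hypnogram: data.frame(label, start_epoch (0-based),
# n_epochs)
hyp_runs <- function(h) {
  r <- rle(h$labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values,
             start_epoch = ends - r$lengths,
             n_epochs = r$lengths,
             stringsAsFactors = FALSE)
}

#' Segment a hypnogram into bouts of one state
#'
#' A bout is a maximal run of consecutive epochs scored as `state`. Any other
#' label - including `ARTIFACT` - terminates a run. With
#' `rules$arousal_tolerant_bouts = TRUE` and `state = "NREM"`, waking runs
#' that qualify as brief arousals (see [count_brief_arousals()]) are bridged:
#' the flanking NREM runs merge into one bout whose duration excludes the
#' waking epochs.
#'
#' @param h A [hypnogram()].
#' @param state One of `"WAKE"`, `"NREM"`, `"REM"`, `"ARTIFACT"`.
#' @param rules A [scoring_rules()]; only consulted for arousal-tolerant
#'   segmentation.
#' @return A `data.frame` with one row per bout: `state`, `start_s` (seconds
#'   from recording start), `duration_s`, `start_epoch` (0-based),
#'   `n_epochs`. Zero rows when the state never occurs.
#' @examples
#' h <- hypnogram(c("NREM", "NREM", "NREM", "WAKE", "NREM"))
#' segment_bouts(h, "NREM")
#' @export
segment_bouts <- function(h, state, rules = scoring_rules(epoch_length_s = h$epoch_length)) {
  stopifnot(inherits(h, "hypnogram"))
  if (!is.character(state) || length(state) != 1L || !state %in% STAGES) {
    stop(sprintf("unknown state '%s' (allowed: %s)",
                 paste(state, collapse = ","), paste(STAGES, collapse = ", ")))
  }
  runs <- hyp_runs(h)
  keep <- runs[runs$label == state, , drop = FALSE]

  if (isTRUE(rules$arousal_tolerant_bouts) && state == "NREM" && nrow(keep) > 1L) {
    ba <- brief_arousal_runs(h, rules)
    # merge NREM runs separated by exactly one qualifying arousal run
    merged <- list()
    cur <- keep[1L, ]
    for (i in seq_len(nrow(keep))[-1L]) {
      gap_start <- cur$start_epoch + cur$n_epochs
      gap_end <- keep$start_epoch[i]
      bridged <- any(ba$start_epoch == gap_start &
                       ba$start_epoch + ba$n_epochs == gap_end)
      if (bridged) {
        cur$n_epochs <- cur$n_epochs + keep$n_epochs[i]  # sleep epochs only
        cur$span_end <- keep$start_epoch[i] + keep$n_epochs[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- keep[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    keep <- do.call(rbind, lapply(merged, function(x) x[c("label", "start_epoch", "n_epochs")]))
  }

  ep <- h$epoch_length
  data.frame(state = rep(state, nrow(keep)),
             start_s = keep$start_epoch * ep,
             duration_s = keep$n_epochs * ep,
             start_epoch = keep$start_epoch,
             n_epochs = keep$n_epochs,
             stringsAsFactors = FALSE)
}

#' State durations per Zeitgeber-time bin
#'
#' Sums epoch time per stage within consecutive ZT bins. An epoch belongs to
#' the bin containing its start, so a bin edge falling mid-epoch assigns the
#' whole epoch to the earlier bin. Artifact time is reported separately and
#' counts toward bin time, so the four columns always sum to the time binned.
#'
#' @param h A [hypnogram()].
#' @param bin_edges_zt Increasing ZT hours delimiting the bins (length >= 2),
#'   within the recording.
#' @return A `data.frame` with one row per bin: `bin_start`, `bin_end` (ZT h),
#'   `wake_min`, `nrem_min`, `rem_min`, `artifact_min`.
#' @export
state_durations <- function(h, bin_edges_zt) {
  stopifnot(inherits(h, "hypnogram"))
  e <- as.numeric(bin_edges_zt)
  if (length(e) < 2L || any(diff(e) <= 0)) {
    stop("bin_edges_zt must be at least two strictly increasing ZT hours")
  }
  rec_end <- h$start_zt + hypnogram_duration(h) / 3600
  if (e[1L] < h$start_zt - 1e-9 || e[length(e)] > rec_end + 1e-9) {
    stop(sprintf("bins [%g, %g] extend outside the recording [ZT%g, ZT%g]",
                 e[1L], e[length(e)], h$start_zt, rec_end))
  }
  zt <- epoch_start_zt(h)
  bin <- findInterval(zt + 1e-12, e)          # 0 = before first edge
  bin[bin == length(e)] <- 0L                 # epoch starting at/after last edge
  ep_min <- h$epoch_length / 60
  out <- data.frame(bin_start = e[-length(e)], bin_end = e[-1L])
  for (st in c("WAKE", "NREM", "REM", "ARTIFACT")) {
    cnt <- tabulate(bin[h$labels == st], nbins = length(e) - 1L)
    out[[paste0(tolower(sub("ARTIFACT", "artifact", st)), "_min")]] <- cnt * ep_min
  }
  names(out) <- c("bin_start", "bin_end", "wake_min", "nrem_min", "rem_min",
                  "artifact_min")
  out
}

#' Sleep latency from a reference time
#'
#' Time from `t0_zt` (e.g. compound administration, snapped forward to the
#' next epoch boundary) to the start of the first bout of `state` that (a)
#' starts at or after the reference and (b) meets the state's minimum
#' duration (NREM >= 30 s, REM >= 20 s under the default rules). When no
#' qualifying bout exists the remaining recording time is returned with
#' `censored = TRUE`.
#'
#' @param h A [hypnogram()].
#' @param state `"NREM"` or `"REM"` (other states use one epoch as minimum).
#' @param t0_zt Reference time, ZT hours, within the recording.
#' @param rules A [scoring_rules()].
#' @return A list: `latency_min` (minutes), `censored` (logical).
#' @export
sleep_latency <- function(h, state, t0_zt,
                          rules = scoring_rules(epoch_length_s = h$epoch_length)) {
  stopifnot(inherits(h, "hypnogram"))
  ep <- h$epoch_length
  total_s <- hypnogram_duration(h)
  off_s <- (t0_zt - h$start_zt) * 3600
  if (off_s < -1e-9 || off_s > total_s + 1e-9) {
    stop(sprintf("t0 (ZT%g) outside the recording", t0_zt))
  }
  t0_s <- ceiling(off_s / ep - 1e-9) * ep     # snap to next epoch boundary
  min_s <- switch(state,
                  NREM = rules$nrem_latency_min_bout_s,
                  REM = rules$rem_latency_min_bout_s,
                  ep)
  bouts <- segment_bouts(h, state, rules)
  ok <- bouts$duration_s >= min_s - 1e-9 & bouts$start_s >= t0_s - 1e-9
  if (any(ok)) {
    list(latency_min = (min(bouts$start_s[ok]) - t0_s) / 60, censored = FALSE)
  } else {
    list(latency_min = (total_s - t0_s) / 60, censored = TRUE)
  }
}

# maximal WAKE runs qualifying as brief arousals: duration in the inclusive
# rules range, immediately flanked by NREM epochs on both sides
brief_arousal_runs <- function(h, rules) {
  runs <- hyp_runs(h)
  ep <- h$epoch_length
  n <- nrow(runs)
  if (n < 3L) return(runs[0L, ])
  i <- 2L:(n - 1L)
  dur <- runs$n_epochs[i] * ep
  ok <- runs$label[i] == "WAKE" &
    dur >= rules$brief_arousal_min_s - 1e-9 &
    dur <= rules$brief_arousal_max_s + 1e-9 &
    runs$label[i - 1L] == "NREM" &
    runs$label[i + 1L] == "NREM"
  runs[i[ok], , drop = FALSE]
}

#' Count brief arousals
#'
#' A brief arousal is a maximal waking run of 20-30 s (inclusive, i.e. 2-3
#' ten-second epochs) whose immediately flanking epochs on both sides are
#' NREM - short awakenings inside consolidated NREM sleep, an index of sleep
#' fragmentation. Runs touching the recording edge never qualify.
#'
#' @param h A [hypnogram()].
#' @param window_zt Optional `c(start, end)` ZT window; only arousals whose
#'   waking run starts inside it are counted. `NULL` counts the whole
#'   recording.
#' @param rules A [scoring_rules()].
#' @return Integer count.
#' @export
count_brief_arousals <- function(h, window_zt = NULL,
                                 rules = scoring_rules(epoch_length_s = h$epoch_length)) {
  stopifnot(inherits(h, "hypnogram"))
  ba <- brief_arousal_runs(h, rules)
  if (is.null(window_zt)) return(nrow(ba))
  w <- as.numeric(window_zt)
  rec_end <- h$start_zt + hypnogram_duration(h) / 3600
  if (length(w) != 2L || w[1L] >= w[2L] ||
      w[1L] < h$start_zt - 1e-9 || w[2L] > rec_end + 1e-9) {
    stop("window_zt must be an increasing ZT pair within the recording")
  }
  start_zt_run <- h$start_zt + ba$start_epoch * h$epoch_length / 3600
  sum(start_zt_run >= w[1L] - 1e-12 & start_zt_run < w[2L] - 1e-12)
}

#' Bout count and mean duration within a window
#'
#' Counts bouts starting within `[window_s[1], window_s[2])` (seconds from
#' recording start) and averages their durations. With no qualifying bouts
#' the mean is `NA`, never zero.
#'
#' @param bouts A bout table from [segment_bouts()].
#' @param window_s `c(start, end)` seconds from recording start; `NULL` uses
#'   all bouts.
#' @return A list: `count`, `mean_duration_s` (`NA` when `count == 0`).
#' @export
bout_statistics <- function(bouts, window_s = NULL) {
  stopifnot(is.data.frame(bouts))
  if (!is.null(window_s)) {
    w <- as.numeric(window_s)
    if (length(w) != 2L || w[1L] >= w[2L]) {
      stop("window_s must be an increasing pair of seconds")
    }
    bouts <- bouts[bouts$start_s >= w[1L] - 1e-9 & bouts$start_s < w[2L] - 1e-9, ,
                   drop = FALSE]
  }
  n <- nrow(bouts)
  list(count = n,
       mean_duration_s = if (n > 0L) mean(bouts$duration_s) else NA_real_)
}

#' All hypnogram metrics for one subject/session
#'
#' Computes, relative to a dosing time `t0_zt`, the cumulative state
#' durations in the requested post-dosing bins, NREM and REM latencies, NREM
#' and REM bout statistics over the first `bout_window_h` hours, and the
#' brief-arousal count over the same window - one row per bin, with the
#' window-level quantities repeated on each row.
#'
#' @param h A [hypnogram()].
#' @param t0_zt Dosing time, ZT hours.
#' @param bins_h Cumulative bin widths in hours post-dosing (default
#'   `c(1, 3, 6)`).
#' @param bout_window_h Continuity-metric window in hours post-dosing
#'   (default 3).
#' @param rules A [scoring_rules()].
#' @param subject_id,condition Identifiers copied into the output.
#' @return A `data.frame` of `SleepMetricsRow`s.
#' @export
sleep_metrics <- function(h, t0_zt, bins_h = c(1, 3, 6), bout_window_h = 3,
                          rules = scoring_rules(epoch_length_s = h$epoch_length),
                          subject_id = NA_character_, condition = NA_character_) {
  stopifnot(inherits(h, "hypnogram"))
  rec_end <- h$start_zt + hypnogram_duration(h) / 3600
  bins_h <- sort(as.numeric(bins_h))
  bins_h <- bins_h[t0_zt + bins_h <= rec_end + 1e-9]
  if (length(bins_h) == 0L) stop("no requested bin fits inside the recording")

  nrem_lat <- sleep_latency(h, "NREM", t0_zt, rules)
  rem_lat <- sleep_latency(h, "REM", t0_zt, rules)
  bw_h <- min(bout_window_h, rec_end - t0_zt)
  w_s <- ((c(t0_zt, t0_zt + bw_h)) - h$start_zt) * 3600
  nrem_bs <- bout_statistics(segment_bouts(h, "NREM", rules), w_s)
  rem_bs <- bout_statistics(segment_bouts(h, "REM", rules), w_s)
  ba <- count_brief_arousals(h, c(t0_zt, t0_zt + bw_h), rules)

  rows <- lapply(bins_h, function(b) {
    sd <- state_durations(h, c(t0_zt, t0_zt + b))
    data.frame(subject_id = subject_id, condition = condition,
               bin_start = t0_zt, bin_end = t0_zt + b,
               wake_min = sd$wake_min, nrem_min = sd$nrem_min,
               rem_min = sd$rem_min, artifact_min = sd$artifact_min,
               nrem_latency_min = nrem_lat$latency_min,
               nrem_latency_censored = nrem_lat$censored,
               rem_latency_min = rem_lat$latency_min,
               rem_latency_censored = rem_lat$censored,
               nrem_bout_count = nrem_bs$count,
               nrem_bout_mean_s = nrem_bs$mean_duration_s,
               rem_bout_count = rem_bs$count,
               rem_bout_mean_s = rem_bs$mean_duration_s,
               brief_arousals = ba,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
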