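#' @keywords internal
"_PACKAGE"

# Canonical stage vocabulary. Everything downstream assumes exactly these
# four labels; readers map dialects onto them or fail.
STAGES <- c("WAKE", "NREM", "REM", "ARTIFACT")

#' Construct a hypnogram
#'
#' A hypnogram is the ordered sequence of scored sleep/wake stages, one label
#' per fixed-length epoch, anchored to Zeitgeber time (ZT; hours since light
#' onset, ZT0 = lights on).
#'
#' @param labels Character vector over `WAKE`, `NREM`, `REM`, `ARTIFACT`
#'   (one element per epoch, in recording order).
#' @param epoch_length Epoch length in seconds (default 10).
#' @param start_zt Recording start in ZT hours (default 0: recording starts
#'   at light onset).
#' @return An object of class `hypnogram`: a list with elements `labels`,
#'   `epoch_length`, `start_zt`.
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "REM"))
#' hypnogram_duration(h)  # seconds
#' @export
hypnogram <- function(labels, epoch_length = 10, start_zt = 0) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- which(!labels %in% STAGES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid stage label '%s' at epoch %d (allowed: %s)",
                 labels[bad[1L]], bad[1L], paste(STAGES, collapse = ", ")))
  }
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L ||
      !is.finite(epoch_length) || epoch_length <= 0) {
    stop("epoch_length must be a single positive number of seconds")
  }
  if (!is.numeric(start_zt) || length(start_zt) != 1L || !is.finite(start_zt)) {
    stop("start_zt must be a single finite number of ZT hours")
  }
  structure(list(labels = labels, epoch_length = epoch_length,
                 start_zt = start_zt),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  dur_h <- length(x$labels) * x$epoch_length / 3600
  cat(sprintf("<hypnogram> %d epochs of %gs (%.2f h), start ZT%.2f\n",
              length(x$labels), x$epoch_length, dur_h, x$start_zt))
  tab <- table(factor(x$labels, levels = STAGES))
  cat(paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Total hypnogram duration in seconds
#' @param h A [hypnogram()].
#' @return Duration in seconds.
#' @export
hypnogram_duration <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  length(h$labels) * h$epoch_length
}

# ZT hour of each epoch start.
epoch_start_zt <- function(h) {
  h$start_zt + (seq_along(h$labels) - 1L) * h$epoch_length / 3600
}

#' Construct an EEG recording
#'
#' Continuous single-channel EEG, amplitude in microvolts, anchored to ZT.
#'
#' @param samples Numeric amplitude series (uV). Must be finite unless
#'   `allow_missing = TRUE`.
#' @param sampling_rate Sampling rate in Hz.
#' @param start_zt Recording start in ZT hours.
#' @param channel_label Channel name (default "EEG").
#' @param allow_missing Permit non-finite samples (amplifier dropouts marked
#'   `NA`/`NaN`); [epoch_psd()] marks the affected epochs missing.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, start_zt = 0,
                          channel_label = "EEG", allow_missing = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain samples")
  if (!isTRUE(allow_missing) && !all(is.finite(samples))) {
    stop(sprintf("recording contains %d non-finite samples",
                 sum(!is.finite(samples))))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 start_zt = start_zt, channel_label = as.character(channel_label)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> '%s': %d samples @ %g Hz (%.2f h), start ZT%.2f\n",
              x$channel_label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate / 3600, x$start_zt))
  invisible(x)
}

#' Scoring rules for latency and fragmentation metrics
#'
#' Bundles the epoch length and the bout/arousal thresholds used by the
#' hypnogram metrics: a NREM sleep latency counts from the first NREM bout of
#' at least `nrem_latency_min_bout_s` (default 30 s), a REM latency from the
#' first REM bout of at least `rem_latency_min_bout_s` (default 20 s), and a
#' brief arousal is a waking run of 20-30 s (inclusive) flanked by NREM on
#' both sides.
#'
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param nrem_latency_min_bout_s Minimum qualifying NREM bout (s).
#' @param rem_latency_min_bout_s Minimum qualifying REM bout (s).
#' @param brief_arousal_min_s,brief_arousal_max_s Inclusive duration range of
#'   a brief arousal (s).
#' @param arousal_tolerant_bouts If `TRUE`, NREM bout segmentation bridges
#'   across brief arousals instead of terminating at them. Default `FALSE`:
#'   bouts are maximal same-label runs.
#' @return An object of class `scoring_rules`.
#' @export
scoring_rules <- function(epoch_length_s = 10,
                          nrem_latency_min_bout_s = 30,
                          rem_latency_min_bout_s = 20,
                          brief_arousal_min_s = 20,
                          brief_arousal_max_s = 30,
                          arousal_tolerant_bouts = FALSE) {
  vals <- c(epoch_length_s, nrem_latency_min_bout_s, rem_latency_min_bout_s,
            brief_arousal_min_s, brief_arousal_max_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scoring-rule durations must be positive and finite")
  }
  if (brief_arousal_min_s > brief_arousal_max_s) {
    stop("brief_arousal_min_s must not exceed brief_arousal_max_s")
  }
  for (v in c(nrem_latency_min_bout_s, rem_latency_min_bout_s)) {
    if (abs(v / epoch_length_s - round(v / epoch_length_s)) > 1e-9) {
      stop("minimum-bout thresholds must be integer multiples of the epoch length")
    }
  }
  structure(list(epoch_length_s = epoch_length_s,
                 nrem_latency_min_bout_s = nrem_latency_min_bout_s,
                 rem_latency_min_bout_s = rem_latency_min_bout_s,
                 brief_arousal_min_s = brief_arousal_min_s,
                 brief_arousal_max_s = brief_arousal_max_s,
                 arousal_tolerant_bouts = isTRUE(arousal_tolerant_bouts)),
            class = "scoring_rules")
}

#' Read scoring rules from a YAML file
#'
#' Keys: `epoch_length_s`, `nrem_latency_min_bout_s`, `rem_latency_min_bout_s`,
#' `brief_arousal_min_s`, `brief_arousal_max_s`, `arousal_tolerant_bouts`.
#' Missing keys take the [scoring_rules()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `scoring_rules` object.
#' @export
read_scoring_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scoring_rules))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown scoring-rules key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(scoring_rules, cfg)
}
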