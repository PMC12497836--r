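# Epoch-wise Welch power spectral density and the quantitative-EEG pipeline:
# relative power per 1-Hz bin, band aggregation, state-conditioned time
# courses, percent change from a within-subject baseline window.

#' Spectral analysis configuration
#'
#' Welch parameters for [epoch_psd()]. Defaults: Hamming window, 4-s
#' segments (0.25 Hz native resolution, so band edges on the 0.5 Hz grid and
#' exact-frequency tones resolve inside a single 1-Hz output bin), 50%
#' overlap, output bins spanning 0.5-100 Hz.
#'
#' @param segment_s Welch segment length, seconds.
#' @param overlap Fractional overlap between consecutive segments in `[0, 1)`.
#' @param window Taper name; only `"hamming"` is supported.
#' @param fmin,fmax Analysis span in Hz; output is 1-Hz bins with centers
#'   `ceiling(fmin) ... fmax`.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(segment_s = 4, overlap = 0.5, window = "hamming",
                            fmin = 0.5, fmax = 100) {
  if (!identical(window, "hamming")) stop("only the Hamming window is supported")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (segment_s <= 0 || fmin <= 0 || fmax <= fmin) {
    stop("segment_s must be positive and 0 < fmin < fmax")
  }
  structure(list(segment_s = segment_s, overlap = overlap, window = window,
                 fmin = fmin, fmax = fmax),
            class = "spectral_config")
}

#' Read spectral configuration from YAML
#' @param path YAML file with keys `segment_s`, `overlap`, `window`, `fmin`,
#'   `fmax` (missing keys take defaults).
#' @return A `spectral_config`.
#' @export
read_spectral_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(spectral_config)))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown spectral config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(spectral_config, cfg)
}

# 1-Hz output bin geometry for a config: centers, lower/upper interval edges
# (bin k covers [k - 0.5, k + 0.5), truncated to [fmin, fmax])
psd_bins <- function(config) {
  centers <- seq(ceiling(config$fmin), floor(config$fmax))
  lower <- pmax(centers - 0.5, config$fmin)
  upper <- pmin(centers + 0.5, config$fmax)
  list(centers = centers, lower = lower, upper = upper)
}

#' Per-epoch Welch power spectral density
#'
#' For each scoring epoch, averages Hamming-windowed, overlapping segment
#' periodograms (Welch's method) and aggregates the native-resolution
#' one-sided density into 1-Hz bins over the analysis span. Normalization is
#' by the window power (`sum(w^2)`) and sampling rate, so a unit-variance
#' white signal yields a flat spectrum whose 0.5-100 Hz total equals the
#' variance falling in that span.
#'
#' Epochs containing non-finite samples are returned as all-`NA` rows and
#' logged via `message()`. Hypnogram and signal may disagree by at most one
#' trailing epoch; the partial epoch is dropped (logged).
#'
#' @param recording An [eeg_recording()] (its sampling rate must be at least
#'   `2 * fmax`).
#' @param h The aligned [hypnogram()].
#' @param config A [spectral_config()].
#' @return A `psd_matrix`: list with `power` (epochs x bins, uV^2),
#'   `bin_centers` (Hz), `bin_lower`, `bin_upper`, `epoch_length`,
#'   `sampling_rate`.
#' @export
epoch_psd <- function(recording, h, config = spectral_config()) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(h, "hypnogram"))
  fs <- recording$sampling_rate
  if (fs < 2 * config$fmax) {
    stop(sprintf("sampling rate %g Hz below Nyquist requirement %g Hz",
                 fs, 2 * config$fmax))
  }
  ep_n <- round(h$epoch_length * fs)
  if (abs(ep_n - h$epoch_length * fs) > 1e-6) {
    stop("epoch length must be a whole number of samples at this rate")
  }
  n_sig_ep <- length(recording$samples) %/% ep_n
  n_hyp <- length(h$labels)
  if (abs(n_sig_ep - n_hyp) > 1L) {
    stop(sprintf("signal (%d epochs) and hypnogram (%d epochs) differ by more than one epoch",
                 n_sig_ep, n_hyp))
  }
  n_use <- min(n_sig_ep, n_hyp)
  if (n_sig_ep != n_hyp) {
    message(sprintf("signal/hypnogram duration mismatch: using %d epochs, trailing partial epoch dropped",
                    n_use))
  }

  nseg <- round(config$segment_s * fs)
  hop <- max(1L, round(nseg * (1 - config$overlap)))
  if (nseg > ep_n) stop("Welch segment longer than one epoch")
  starts <- seq(0L, ep_n - nseg, by = hop)
  w <- signal::hamming(nseg)
  U <- sum(w^2)
  freqs <- (0:(nseg %/% 2)) * fs / nseg
  df <- fs / nseg
  # native bins tile the half-open analysis span [fmin, fmax), matching the
  # half-open 1-Hz output bins exactly
  keep <- which(freqs >= config$fmin - 1e-9 & freqs < config$fmax - 1e-9)
  bins <- psd_bins(config)
  grp <- floor(freqs[keep] + 0.5 + 1e-9)          # 1-Hz bin index per native bin
  grp_idx <- match(grp, bins$centers)

  power <- matrix(NA_real_, nrow = n_hyp, ncol = length(bins$centers))
  n_bad <- 0L
  chunk <- 512L
  for (c0 in seq(1L, n_use, by = chunk)) {
    eps <- c0:min(c0 + chunk - 1L, n_use)
    # segment matrix: nseg x (n_segments_per_epoch * n_epochs_in_chunk)
    base <- rep((eps - 1L) * ep_n, each = length(starts)) +
      rep(starts, times = length(eps))
    idx <- outer(seq_len(nseg), base, "+")
    X <- matrix(recording$samples[idx], nrow = nseg)
    bad_col <- !is.finite(colSums(X))
    bad_ep <- unique(rep(eps, each = length(starts))[bad_col])
    n_bad <- n_bad + length(bad_ep)
    if (any(bad_col)) X[, bad_col] <- 0
    spec <- Mod(stats::mvfft(X * w))^2 / (fs * U)
    spec <- spec[keep, , drop = FALSE]
    scale2 <- ifelse(freqs[keep] > 1e-12 & freqs[keep] < fs / 2 - 1e-12, 2, 1)
    spec <- spec * scale2
    binned <- rowsum(spec * df, group = grp_idx)       # bins x segments
    # average segments within each epoch
    nsg <- length(starts)
    ep_mean <- vapply(seq_along(eps), function(i) {
      cols <- ((i - 1L) * nsg + 1L):(i * nsg)
      rowMeans(binned[, cols, drop = FALSE])
    }, numeric(nrow(binned)))
    power[eps, ] <- t(ep_mean)
    if (length(bad_ep) > 0L) power[bad_ep, ] <- NA_real_
  }
  if (n_bad > 0L) {
    message(sprintf("%d epoch(s) contained non-finite samples and were marked missing", n_bad))
  }
  structure(list(power = power, bin_centers = bins$centers,
                 bin_lower = bins$lower, bin_upper = bins$upper,
                 epoch_length = h$epoch_length, sampling_rate = fs),
            class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf("<psd_matrix> %d epochs x %d one-Hz bins (%g-%g Hz), %d missing epoch(s)\n",
              nrow(x$power), length(x$bin_centers), x$bin_lower[1L],
              x$bin_upper[length(x$bin_upper)], sum(!stats::complete.cases(x$power))))
  invisible(x)
}

#' Relative power per frequency bin
#'
#' Divides each epoch's bin powers by the epoch's total over the analysis
#' span, so rows sum to one. Rows with zero or missing total propagate as
#' `NA` (never zero-filled).
#'
#' @param psd A `psd_matrix` from [epoch_psd()], or a numeric matrix/vector
#'   of bin powers.
#' @return A matrix (or vector) of fractions with the same shape.
#' @export
relative_power <- function(psd) {
  p <- if (inherits(psd, "psd_matrix")) psd$power else psd
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1L)
  if (any(p < 0, na.rm = TRUE)) stop("negative power values")
  tot <- rowSums(p)
  out <- p / tot
  out[!is.finite(tot) | tot <= 0, ] <- NA_real_
  if (vec) out[1L, ] else out
}

#' EEG frequency-band scheme
#'
#' The conventional rodent qEEG bands as half-open intervals `[low, high)`
#' Hz: delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-16, beta 16-24, low
#' gamma 30-50, high gamma 50-100, total gamma 30-100. The 24-30 Hz gap
#' between beta and low gamma is deliberate (kept out of every named band).
#'
#' @param ... Name-value pairs `name = c(low, high)` replacing the default
#'   scheme entirely when supplied.
#' @return A named list of `c(low, high)` pairs, class `band_scheme`.
#' @export
band_scheme <- function(...) {
  bands <- list(...)
  if (length(bands) == 0L) {
    bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                  sigma = c(12, 16), beta = c(16, 24), low_gamma = c(30, 50),
                  high_gamma = c(50, 100), total_gamma = c(30, 100))
  }
  for (nm in names(bands)) {
    b <- as.numeric(bands[[nm]])
    if (length(b) != 2L || b[1L] >= b[2L]) {
      stop(sprintf("band '%s' must be c(low, high) with low < high", nm))
    }
    if (b[1L] < 0.5 - 1e-9 || b[2L] > 100 + 1e-9) {
      stop(sprintf("band '%s' [%g, %g) lies outside the 0.5-100 Hz span",
                   nm, b[1L], b[2L]))
    }
    bands[[nm]] <- b
  }
  structure(bands, class = "band_scheme")
}

#' Read a band scheme from YAML (`name: [low_hz, high_hz]`)
#' @param path YAML file path.
#' @return A `band_scheme`.
#' @export
read_band_scheme <- function(path) {
  do.call(band_scheme, yaml::read_yaml(path))
}

# bins x bands weight matrix: fraction of each 1-Hz bin interval overlapped
# by each band. A bin straddling a band edge contributes proportionally, so
# the non-overlapping bands plus the 24-30 Hz remainder tile the span and
# their fractions sum to 1.
band_weights <- function(scheme, lower, upper) {
  W <- vapply(scheme, function(b) {
    ov <- pmax(0, pmin(b[2L], upper) - pmax(b[1L], lower))
    ov / (upper - lower)
  }, numeric(length(lower)))
  dimnames(W) <- list(NULL, names(scheme))
  W
}

#' Band power from relative (or absolute) bin power
#'
#' Aggregates 1-Hz bin values into named bands, weighting each bin by the
#' fraction of its interval inside the band.
#'
#' @param rel A vector or matrix of per-bin values (columns = 1-Hz bins of a
#'   `psd_matrix`), or a `psd_matrix`.
#' @param scheme A [band_scheme()].
#' @param config A [spectral_config()] describing the bin geometry when
#'   `rel` is a bare vector/matrix.
#' @return Named vector (or epochs x bands matrix) of band values.
#' @export
band_power <- function(rel, scheme = band_scheme(), config = spectral_config()) {
  if (inherits(rel, "psd_matrix")) {
    lower <- rel$bin_lower; upper <- rel$bin_upper
    rel <- rel$power
  } else {
    bins <- psd_bins(config)
    lower <- bins$lower; upper <- bins$upper
  }
  stopifnot(inherits(scheme, "band_scheme"))
  vec <- is.null(dim(rel))
  if (vec) rel <- matrix(rel, nrow = 1L)
  if (ncol(rel) != length(lower)) {
    stop(sprintf("expected %d bins, got %d columns", length(lower), ncol(rel)))
  }
  out <- rel %*% band_weights(scheme, lower, upper)
  if (vec) out[1L, ] else out
}

#' State-conditioned band-power time course
#'
#' For each ZT bin and each arousal state (wake, NREM, REM; artifact epochs
#' are excluded), the mean over that state's epochs of the per-epoch relative
#' band power. Bins with no epochs of a state are `NA`.
#'
#' @param psd A `psd_matrix` aligned to `h`.
#' @param h The [hypnogram()].
#' @param scheme A [band_scheme()].
#' @param bin_edges_zt Increasing ZT hours delimiting the time bins.
#' @param subject_id Identifier copied into the output.
#' @return A `data.frame`: `subject_id`, `state`, `band`, `bin_start`,
#'   `bin_end`, `value` (mean relative power, fraction), `n_epochs`.
#' @export
state_band_timecourse <- function(psd, h, scheme = band_scheme(),
                                  bin_edges_zt, subject_id = NA_character_) {
  stopifnot(inherits(psd, "psd_matrix"), inherits(h, "hypnogram"))
  if (nrow(psd$power) != length(h$labels)) {
    stop(sprintf("psd (%d rows) not aligned to hypnogram (%d epochs)",
                 nrow(psd$power), length(h$labels)))
  }
  e <- as.numeric(bin_edges_zt)
  if (length(e) < 2L || any(diff(e) <= 0)) {
    stop("bin_edges_zt must be at least two strictly increasing ZT hours")
  }
  rel <- relative_power(psd)
  bands <- rel %*% band_weights(scheme, psd$bin_lower, psd$bin_upper)
  colnames(bands) <- names(scheme)
  zt <- epoch_start_zt(h)
  bin <- findInterval(zt + 1e-12, e)
  bin[bin == length(e)] <- 0L

  states <- c("WAKE", "NREM", "REM")
  out <- expand.grid(band = names(scheme), state = states,
                     bin = seq_len(length(e) - 1L), stringsAsFactors = FALSE)
  vals <- mapply(function(bd, st, bi) {
    sel <- h$labels == st & bin == bi & stats::complete.cases(bands)
    if (!any(sel)) return(c(NA_real_, 0))
    c(mean(bands[sel, bd]), sum(sel))
  }, out$band, out$state, out$bin)
  data.frame(subject_id = subject_id, state = out$state, band = out$band,
             bin_start = e[out$bin], bin_end = e[out$bin + 1L],
             value = vals[1L, ], n_epochs = as.integer(vals[2L, ]),
             stringsAsFactors = FALSE)
}

#' Normalize a band time course to a within-subject baseline window
#'
#' Computes, per subject, state and band, the baseline as the epoch-weighted
#' mean of the time-course values whose bins fall entirely inside
#' `baseline_window_zt`, then expresses every bin as percent change,
#' `100 * (value - baseline) / baseline`. Series with a missing or
#' non-positive baseline propagate `NA` (logged).
#'
#' @param timecourse Output of [state_band_timecourse()].
#' @param baseline_window_zt `c(start, end)` ZT hours of the pre-dosing
#'   baseline (default `c(0, 2)`: the standard 2-h baseline; combination
#'   designs dosing at ZT1 use `c(0, 1)`).
#' @return The time course with `baseline` and `pct_change` columns added.
#' @export
baseline_normalize <- function(timecourse, baseline_window_zt = c(0, 2)) {
  need <- c("subject_id", "state", "band", "bin_start", "bin_end", "value",
            "n_epochs")
  if (!all(need %in% names(timecourse))) {
    stop("timecourse must come from state_band_timecourse()")
  }
  w <- as.numeric(baseline_window_zt)
  if (length(w) != 2L || w[1L] >= w[2L]) {
    stop("baseline_window_zt must be an increasing ZT pair")
  }
  key <- interaction(timecourse$subject_id, timecourse$state,
                     timecourse$band, drop = TRUE)
  in_base <- timecourse$bin_start >= w[1L] - 1e-9 &
    timecourse$bin_end <= w[2L] + 1e-9 & !is.na(timecourse$value)
  base_num <- tapply(ifelse(in_base, timecourse$value * timecourse$n_epochs, 0),
                     key, sum)
  base_den <- tapply(ifelse(in_base, timecourse$n_epochs, 0), key, sum)
  baseline <- as.numeric(base_num / base_den)[match(key, names(base_num))]
  baseline[!is.finite(baseline) | baseline <= 0] <- NA_real_
  out <- timecourse
  out$baseline <- baseline
  out$pct_change <- 100 * (out$value - baseline) / baseline
  n_miss <- length(unique(key[is.na(baseline)]))
  if (n_miss > 0L) {
    message(sprintf("%d series have no usable baseline in ZT %g-%g; percent change is NA",
                    n_miss, w[1L], w[2L]))
  }
  out
}
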