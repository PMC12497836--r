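# Semi-Markov sleep-architecture simulator, surrogate EEG synthesizer, and
# Poisson behavior model with a shared severity latent. The generator's
# defaults define the study conditions every validation exercise runs under.

#' Sleep-architecture parameters for the semi-Markov simulator
#'
#' State bouts are drawn from exponential distributions whose means switch
#' between light and dark phase (the 12:12 cycle's only circadian structure
#' modeled here); transitions follow a propensity matrix in which REM is
#' enterable only from NREM. Defaults are literature-typical for adult rats:
#' light-phase sleep predominance (roughly 60% NREM / 8% REM occupancy in
#' the light phase, wake-dominant dark phase).
#'
#' @param mean_bout_s Named list with `light` and `dark` numeric vectors of
#'   mean bout durations (s) for `WAKE`, `NREM`, `REM`.
#' @param propensity 3x3 transition propensity matrix (rows = from, columns
#'   = to, dimnames over WAKE/NREM/REM). Diagonal must be zero and
#'   `WAKE -> REM` must be zero; rows are normalized.
#' @param artifact_rate Fraction of epochs independently overwritten as
#'   ARTIFACT, in `[0, 0.05]`. Default 0.002 (clean telemetry recordings).
#' @param epoch_length Scoring epoch, seconds.
#' @return A `sleep_architecture_params` object.
#' @export
sleep_architecture_params <- function(
    mean_bout_s = list(light = c(WAKE = 150, NREM = 300, REM = 100),
                       dark = c(WAKE = 600, NREM = 180, REM = 80)),
    propensity = matrix(c(0, 1, 0,
                          0.65, 0, 0.35,
                          0.8, 0.2, 0),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("WAKE", "NREM", "REM"),
                                        c("WAKE", "NREM", "REM"))),
    artifact_rate = 0.002,
    epoch_length = 10) {
  st <- c("WAKE", "NREM", "REM")
  for (ph in c("light", "dark")) {
    m <- mean_bout_s[[ph]]
    if (is.null(m) || !all(st %in% names(m)) || any(m[st] <= 0)) {
      stop(sprintf("mean_bout_s$%s must give positive means for WAKE/NREM/REM", ph))
    }
  }
  propensity <- as.matrix(propensity)
  if (!identical(dim(propensity), c(3L, 3L)) ||
      !identical(rownames(propensity), st) || !identical(colnames(propensity), st)) {
    stop("propensity must be a 3x3 matrix with WAKE/NREM/REM dimnames")
  }
  if (any(propensity < 0) || any(diag(propensity) != 0)) {
    stop("propensities must be non-negative with a zero diagonal")
  }
  if (propensity["WAKE", "REM"] != 0) {
    stop("REM is enterable only from NREM: propensity WAKE -> REM must be 0")
  }
  if (any(rowSums(propensity) <= 0)) stop("every state needs an exit propensity")
  propensity <- propensity / rowSums(propensity)
  if (artifact_rate < 0 || artifact_rate > 0.05) {
    stop("artifact_rate must lie in [0, 0.05]")
  }
  structure(list(mean_bout_s = lapply(mean_bout_s, function(m) m[st]),
                 propensity = propensity, artifact_rate = artifact_rate,
                 epoch_length = epoch_length),
            class = "sleep_architecture_params")
}

#' Intervention effect on sleep architecture
#'
#' A time-limited multiplicative perturbation starting at `onset_zt`. The
#' wake-propensity multiplier scales the wake drive as a whole: both the
#' transition weights into WAKE and the WAKE mean bout duration (with
#' WAKE -> NREM the only exit from wake, transition weights alone could not
#' lengthen waking or shorten sleep latency). Bout-mean multipliers scale the
#' NREM and REM exponential means. `latency_delay_min` forces a waking bout
#' of that mean (gamma-distributed, shape 4) immediately at onset,
#' reproducing a sleep-latency phenotype directly.
#'
#' @param onset_zt Onset, ZT hours.
#' @param duration_h Duration, hours (> 0).
#' @param wake_propensity_mult,nrem_bout_mult,rem_bout_mult Positive
#'   multipliers (1 = no effect).
#' @param latency_delay_min Mean of the forced-wake delay at onset, minutes
#'   (0 = none).
#' @param label Free-text label (compound name).
#' @return An `intervention_effect` object.
#' @export
intervention_effect <- function(onset_zt, duration_h,
                                wake_propensity_mult = 1,
                                nrem_bout_mult = 1,
                                rem_bout_mult = 1,
                                latency_delay_min = 0,
                                label = "intervention") {
  if (duration_h <= 0) stop("duration_h must be positive")
  if (any(c(wake_propensity_mult, nrem_bout_mult, rem_bout_mult) <= 0)) {
    stop("multipliers must be positive")
  }
  if (latency_delay_min < 0) stop("latency_delay_min must be non-negative")
  structure(list(onset_zt = onset_zt, duration_h = duration_h,
                 wake_propensity_mult = wake_propensity_mult,
                 nrem_bout_mult = nrem_bout_mult,
                 rem_bout_mult = rem_bout_mult,
                 latency_delay_min = latency_delay_min, label = label),
            class = "intervention_effect")
}

#' Intervention presets for the compounds the designs emulate
#'
#' Dose-scaled presets: `"lactic_acid"` (transient 1.5-h wake promotion with
#' NREM/REM suppression, concentration in percent), `"morphine"` (4-h
#' NREM/REM suppression with a dose-scaled sleep-latency delay),
#' `"meloxicam"` (null: no sleep effect), `"at403"` (6-h NREM promotion with
#' REM suppression and reduced wake drive). A zero dose returns a null
#' effect for any compound.
#'
#' Every dose - including vehicle - carries a handling arousal: the
#' injection itself forces a waking bout whose mean is
#' `handling_delay_min` scaled by the compound's wake-drive multiplier, so a
#' sedative shortens the post-injection arousal (and hence sleep latency)
#' while a wake-promoting compound lengthens it. Morphine adds a
#' dose-scaled pharmacological delay on top.
#'
#' @param compound One of `"lactic_acid"`, `"morphine"`, `"meloxicam"`,
#'   `"at403"`.
#' @param dose Dose (mg/kg) or concentration (percent) depending on
#'   compound.
#' @param onset_zt Dosing time, ZT hours (default 2).
#' @param handling_delay_min Mean forced-wake arousal from the injection
#'   procedure, minutes (default 8).
#' @return A list with one [intervention_effect()].
#' @export
intervention_preset <- function(compound, dose, onset_zt = 2,
                                handling_delay_min = 8) {
  compound <- match.arg(compound, c("lactic_acid", "morphine", "meloxicam",
                                    "at403"))
  wake_mult <- switch(compound,
    lactic_acid = 1 + 0.36 * dose,
    morphine = 1 + 0.20 * dose,
    meloxicam = 1,
    at403 = 1 / (1 + 9 * dose))
  delay <- handling_delay_min * wake_mult +
    if (compound == "morphine") min(90, 12 * dose) else 0
  eff <- switch(compound,
    lactic_acid = intervention_effect(
      onset_zt, duration_h = 1.5,
      wake_propensity_mult = wake_mult,
      nrem_bout_mult = 1 / (1 + 0.18 * dose),
      rem_bout_mult = 1 / (1 + 0.33 * dose),
      latency_delay_min = delay,
      label = compound),
    morphine = intervention_effect(
      onset_zt, duration_h = 4,
      wake_propensity_mult = wake_mult,
      nrem_bout_mult = 1 / (1 + 0.12 * dose),
      rem_bout_mult = 1 / (1 + 0.25 * dose),
      latency_delay_min = delay,
      label = compound),
    meloxicam = intervention_effect(
      onset_zt, duration_h = 4, latency_delay_min = delay, label = compound),
    at403 = intervention_effect(
      onset_zt, duration_h = 6,
      wake_propensity_mult = wake_mult,
      nrem_bout_mult = 1 + 5 * dose,
      rem_bout_mult = 1 / (1 + 8 * dose),
      latency_delay_min = delay,
      label = compound)
  )
  list(eff)
}

#' Read an intervention effect from a YAML preset file
#' @param path YAML file with the [intervention_effect()] fields.
#' @return A list with one `intervention_effect`.
#' @export
read_intervention <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(intervention_effect)))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown intervention key(s): %s", paste(unknown, collapse = ", ")))
  }
  list(do.call(intervention_effect, cfg))
}

# multipliers active at ZT hour `zt`
active_multipliers <- function(interventions, zt) {
  out <- c(wake = 1, nrem = 1, rem = 1)
  for (iv in interventions) {
    if (zt >= iv$onset_zt && zt < iv$onset_zt + iv$duration_h) {
      out["wake"] <- out["wake"] * iv$wake_propensity_mult
      out["nrem"] <- out["nrem"] * iv$nrem_bout_mult
      out["rem"] <- out["rem"] * iv$rem_bout_mult
    }
  }
  out
}

#' Simulate a hypnogram by semi-Markov draw
#'
#' Draws alternating state bouts: durations from exponential distributions
#' with phase- and intervention-modulated means, rounded to whole epochs
#' (minimum one); transitions from the propensity matrix with REM enterable
#' only from NREM; artifact epochs overwritten independently at the artifact
#' rate. Deterministic under a fixed seed.
#'
#' @param params A [sleep_architecture_params()].
#' @param interventions List of [intervention_effect()]s (default none).
#' @param hours Recording length, hours.
#' @param seed RNG seed.
#' @param start_zt Recording start, ZT hours (default 0, light onset).
#' @param initial_state Starting state (default `"WAKE"`).
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(params, interventions = list(), hours = 24,
                               seed = 1, start_zt = 0,
                               initial_state = "WAKE") {
  stopifnot(inherits(params, "sleep_architecture_params"), hours > 0)
  if (inherits(interventions, "intervention_effect")) {
    interventions <- list(interventions)
  }
  ep <- params$epoch_length
  n_target <- round(hours * 3600 / ep)
  states <- c("WAKE", "NREM", "REM")

  delayed <- Filter(function(iv) iv$latency_delay_min > 0, interventions)
  pend <- data.frame(
    onset_zt = vapply(delayed, `[[`, numeric(1), "onset_zt"),
    delay_min = vapply(delayed, `[[`, numeric(1), "latency_delay_min"))
  pend <- pend[order(pend$onset_zt), , drop = FALSE]
  pend <- pend[pend$onset_zt >= start_zt & pend$onset_zt < start_zt + hours, ,
               drop = FALSE]

  with_preserved_seed(seed, {
    run_state <- character(4096); run_len <- integer(4096); n_run <- 0L
    push <- function(st, n) {
      n_run <<- n_run + 1L
      if (n_run > length(run_state)) {
        length(run_state) <<- 2L * length(run_state)
        length(run_len) <<- 2L * length(run_len)
      }
      run_state[n_run] <<- st
      run_len[n_run] <<- n
    }
    state <- match.arg(initial_state, states)
    t_ep <- 0L
    p_i <- 1L
    while (t_ep < n_target) {
      zt <- start_zt + t_ep * ep / 3600
      phase <- if ((zt %% 24) < 12) "light" else "dark"
      mult <- active_multipliers(interventions, zt)
      m <- params$mean_bout_s[[phase]][state]
      m <- m * switch(state, WAKE = mult["wake"], NREM = mult["nrem"],
                      REM = mult["rem"])
      n_ep <- max(1L, as.integer(round(stats::rexp(1, 1 / m) / ep)))

      # a dosing event with a latency delay truncates the current bout and
      # forces a waking bout of the drawn delay
      if (p_i <= nrow(pend)) {
        onset_ep <- (pend$onset_zt[p_i] - start_zt) * 3600 / ep
        if (onset_ep < t_ep + n_ep) {
          n_ep <- max(0L, as.integer(floor(onset_ep)) - t_ep)
          if (n_ep > 0L) push(state, n_ep)
          t_ep <- t_ep + n_ep
          # gamma(shape 4): mean = delay, sd = delay / 2 - an injection
          # arousal is far less dispersed than an exponential draw
          delay_s <- stats::rgamma(1, shape = 4,
                                   rate = 4 / (pend$delay_min[p_i] * 60))
          n_wake <- max(1L, as.integer(round(delay_s / ep)))
          push("WAKE", n_wake)
          t_ep <- t_ep + n_wake
          state <- "WAKE"
          p_i <- p_i + 1L
          next
        }
      }

      push(state, n_ep)
      t_ep <- t_ep + n_ep
      zt_end <- start_zt + t_ep * ep / 3600
      w <- params$propensity[state, ]
      w["WAKE"] <- w["WAKE"] * active_multipliers(interventions, zt_end)["wake"]
      state <- sample(states, 1L, prob = w)
    }
    labels <- rep(run_state[seq_len(n_run)], run_len[seq_len(n_run)])
    labels <- labels[seq_len(n_target)]
    art <- stats::runif(n_target) < params$artifact_rate
    labels[art] <- "ARTIFACT"
    hypnogram(labels, epoch_length = ep, start_zt = start_zt)
  })
}

#' Analytic stationary state occupancy of the simulator
#'
#' Long-run fraction of time in each state under fixed-phase parameters:
#' `occupancy_i = pi_i * mu_i / sum_j pi_j * mu_j`, with `pi` the stationary
#' distribution of the embedded transition chain and `mu` the expected bout
#' length. With `epoch_rounded = TRUE` (default), `mu` is the expectation of
#' the epoch-rounded exponential actually drawn,
#' `E[max(1, round(X / ep))] * ep`.
#'
#' @param params A [sleep_architecture_params()].
#' @param phase `"light"` or `"dark"`.
#' @param epoch_rounded Account for rounding bout durations to whole epochs.
#' @return Named numeric vector of occupancies over WAKE/NREM/REM (sums to
#'   1; artifact overwriting is uniform and does not change the ratio).
#' @export
stationary_occupancy <- function(params, phase = "light", epoch_rounded = TRUE) {
  P <- params$propensity
  # stationary distribution of the embedded chain: left eigenvector
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i])
  pi_ <- pi_ / sum(pi_)
  m <- params$mean_bout_s[[phase]]
  ep <- params$epoch_length
  mu <- if (epoch_rounded) {
    vapply(m, function(mm) {
      a <- ep / mm
      (1 + exp(-1.5 * a) / (1 - exp(-a))) * ep
    }, numeric(1))
  } else m
  occ <- pi_ * mu
  stats::setNames(occ / sum(occ), rownames(P))
}

#' State-typical EEG spectral templates
#'
#' Target relative band-power fractions per state plus a `1/f` exponent for
#' the unshaped background: wake is broadband with appreciable gamma, NREM
#' delta-dominant with a sigma (spindle-range) contribution, REM
#' theta-dominant. Fractions per state must lie in `[0, 1]` and sum to at
#' most 1; the remainder is assigned to the 24-30 Hz gap between beta and
#' low gamma.
#'
#' @param templates Named list per state (`WAKE`, `NREM`, `REM`) of named
#'   band-fraction vectors over the non-overlapping [band_scheme()] bands.
#' @param one_over_f Spectral background exponent (power ~ 1/f^a).
#' @return A `spectral_template` object.
#' @export
spectral_template <- function(
    templates = list(
      WAKE = c(delta = 0.18, theta = 0.22, alpha = 0.12, sigma = 0.08,
               beta = 0.12, low_gamma = 0.10, high_gamma = 0.08),
      NREM = c(delta = 0.55, theta = 0.14, alpha = 0.08, sigma = 0.10,
               beta = 0.05, low_gamma = 0.03, high_gamma = 0.02),
      REM = c(delta = 0.15, theta = 0.45, alpha = 0.10, sigma = 0.06,
              beta = 0.08, low_gamma = 0.08, high_gamma = 0.05)),
    one_over_f = 1) {
  scheme <- band_scheme()
  for (st in c("WAKE", "NREM", "REM")) {
    fr <- templates[[st]]
    if (is.null(fr)) stop(sprintf("missing template for state %s", st))
    if (!all(names(fr) %in% names(scheme))) {
      bad <- setdiff(names(fr), names(scheme))
      stop(sprintf("unknown template band(s) for %s: %s", st,
                   paste(bad, collapse = ", ")))
    }
    if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-9) {
      stop(sprintf("template fractions for %s must lie in [0,1] and sum to <= 1", st))
    }
  }
  structure(list(templates = templates, one_over_f = one_over_f,
                 scheme = scheme),
            class = "spectral_template")
}

# target one-sided power density over frequency grid f for one state
template_density <- function(template, state, f) {
  fr <- template$templates[[state]]
  scheme <- template$scheme
  dens <- numeric(length(f))
  support <- f >= 0.5 & f <= 100
  base <- ifelse(support, 1 / pmax(f, 0.5)^template$one_over_f, 0)
  assigned <- rep(FALSE, length(f))
  for (nm in names(fr)) {
    b <- scheme[[nm]]
    sel <- support & f >= b[1L] & f < b[2L]
    if (!any(sel)) {
      stop(sprintf("template band %s resolves to no frequencies", nm))
    }
    dens[sel] <- base[sel] * fr[nm] / sum(base[sel])
    assigned <- assigned | sel
  }
  rest <- support & !assigned
  leftover <- 1 - sum(fr)
  if (any(rest) && leftover > 0) {
    dens[rest] <- base[rest] * leftover / sum(base[rest])
  }
  dens
}

#' Synthesize surrogate EEG from a hypnogram
#'
#' Per epoch, Gaussian noise is spectrally shaped in the frequency domain to
#' the state's template density (artifact epochs use the wake template), and
#' adjacent epochs are cross-faded with complementary square-root ramps over
#' `crossfade_s` so epoch splices introduce no step artifacts. Deterministic
#' under a fixed seed.
#'
#' @param h A [hypnogram()].
#' @param template A [spectral_template()].
#' @param sampling_rate Hz (>= 200 so the 100 Hz analysis edge is below
#'   Nyquist).
#' @param seed RNG seed.
#' @param amplitude_uV Root-mean-square target amplitude (uV).
#' @param crossfade_s Cross-fade length at epoch boundaries, seconds.
#' @return An [eeg_recording()] aligned to `h`.
#' @export
synthesize_eeg <- function(h, template = spectral_template(),
                           sampling_rate = 500, seed = 1,
                           amplitude_uV = 50, crossfade_s = 0.1) {
  stopifnot(inherits(h, "hypnogram"), inherits(template, "spectral_template"))
  fs <- sampling_rate
  if (fs < 200) stop("sampling_rate must be at least 200 Hz")
  ep <- h$epoch_length
  N <- round(ep * fs)
  w <- round(crossfade_s * fs)
  Ne <- N + w
  n_ep <- length(h$labels)

  # shaping amplitude per state on the extended-epoch FFT grid
  f_half <- (0:(Ne %/% 2)) * fs / Ne
  states <- c("WAKE", "NREM", "REM")
  amp <- lapply(stats::setNames(states, states), function(st) {
    dens <- template_density(template, st, f_half)
    dens <- dens / sum(dens) * amplitude_uV^2      # total variance target
    a_half <- sqrt(dens)
    # mirror to full FFT length (conjugate-symmetric real gain)
    if (Ne %% 2 == 0) c(a_half, rev(a_half[2:(length(a_half) - 1L)]))
    else c(a_half, rev(a_half[-1L]))
  })

  lab <- ifelse(h$labels == "ARTIFACT", "WAKE", h$labels)
  ramp_up <- if (w > 0) sqrt(seq(0, 1, length.out = w)) else numeric(0)
  ramp_dn <- rev(ramp_up)

  with_preserved_seed(seed, {
    out <- numeric(n_ep * N)
    chunk <- 256L
    for (c0 in seq(1L, n_ep, by = chunk)) {
      eps <- c0:min(c0 + chunk - 1L, n_ep)
      G <- matrix(stats::rnorm(Ne * length(eps)), Ne)
      X <- stats::mvfft(G)
      for (st in states) {
        cols <- which(lab[eps] == st)
        if (length(cols) > 0L) {
          X[, cols] <- X[, cols] * amp[[st]]
        }
      }
      # the shaping gain is real and symmetric, so the inverse FFT is real;
      # 1/sqrt(2 Ne) makes the output variance equal the template total
      Y <- Re(stats::mvfft(X, inverse = TRUE)) / sqrt(2 * Ne)
      for (j in seq_along(eps)) {
        k <- eps[j]
        y <- Y[, j]
        if (w > 0) {
          y[seq_len(w)] <- y[seq_len(w)] * ramp_up
          y[(Ne - w + 1L):Ne] <- y[(Ne - w + 1L):Ne] * ramp_dn
        }
        p0 <- (k - 1L) * N - w %/% 2L
        lo <- max(1L, p0 + 1L); hi <- min(n_ep * N, p0 + Ne)
        src <- (lo - p0):(hi - p0)
        out[lo:hi] <- out[lo:hi] + y[src]
      }
    }
    eeg_recording(out, sampling_rate = fs, start_zt = h$start_zt,
                  channel_label = "EEG_synthetic")
  })
}

#' Behavior-count model
#'
#' Poisson counts per 30-minute observation window with log-linear
#' concentration terms and a shared per-animal-session severity latent that
#' scales stretching up while (via the cohort simulator) intensifying the
#' noxious stimulus's wake promotion, so stretching and NREM duration are
#' inversely coupled across animals.
#'
#' @param base_rates Baseline Poisson rates per 30 min for `stretching`,
#'   `rearing`, `grooming`.
#' @param conc_slopes Log-linear slopes per unit concentration (percent):
#'   stretching up, rearing and grooming suppressed.
#' @param severity_sd SD of the per-session severity latent.
#' @param severity_behavior Log-rate increment of stretching per severity
#'   unit (expressed only when a noxious stimulus is present).
#' @param severity_sleep Log-multiplier of the noxious intervention's wake
#'   promotion (and NREM suppression) per severity unit.
#' @return A `behavior_model` object.
#' @export
behavior_model <- function(base_rates = c(stretching = 3.5, rearing = 18,
                                          grooming = 12),
                           conc_slopes = c(stretching = 0.40,
                                           rearing = -0.35,
                                           grooming = -0.25),
                           severity_sd = 1.5,
                           severity_behavior = 0.35,
                           severity_sleep = 0.8) {
  if (any(base_rates < 0)) stop("base rates must be non-negative")
  structure(list(base_rates = base_rates, conc_slopes = conc_slopes,
                 severity_sd = severity_sd,
                 severity_behavior = severity_behavior,
                 severity_sleep = severity_sleep),
            class = "behavior_model")
}

#' Cohort design for the simulator
#'
#' Within-subject crossover: every subject receives every condition, in an
#' order counterbalanced by a cyclic Latin square, with sessions separated by
#' a washout.
#'
#' @param n_subjects Number of subjects.
#' @param compound Compound for [intervention_preset()].
#' @param doses Numeric dose/concentration per condition (0 = vehicle).
#' @param dosing_zt Dosing time, ZT hours.
#' @param hours Recording length per session.
#' @param washout_days Days between sessions (>= 3).
#' @param latin_square Optional custom order matrix (rows = order patterns,
#'   columns = conditions); must have at least as many columns as
#'   conditions.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(n_subjects, compound, doses, dosing_zt = 2,
                              hours = 24, washout_days = 3,
                              latin_square = NULL) {
  k <- length(doses)
  if (k < 1L || n_subjects < 1L) stop("need at least one subject and condition")
  if (washout_days < 3) stop("washout between sessions must be at least 3 days")
  if (is.null(latin_square)) {
    latin_square <- outer(seq_len(k), seq_len(k),
                          function(i, j) ((i + j - 2L) %% k) + 1L)
  } else {
    latin_square <- as.matrix(latin_square)
    if (ncol(latin_square) < k) {
      stop(sprintf("Latin square has %d columns for %d conditions",
                   ncol(latin_square), k))
    }
  }
  structure(list(n_subjects = n_subjects, compound = compound, doses = doses,
                 dosing_zt = dosing_zt, hours = hours,
                 washout_days = washout_days, latin_square = latin_square),
            class = "experiment_design")
}

#' Simulate a full crossover cohort
#'
#' For every subject x condition session: draws the severity latent, builds
#' the dose's intervention (severity-scaled for a noxious `lactic_acid`
#' stimulus), simulates the hypnogram, and draws behavior counts. Optionally
#' synthesizes surrogate EEG and/or writes all outputs in the package's file
#' dialects.
#'
#' @param design An [experiment_design()].
#' @param params A [sleep_architecture_params()].
#' @param bmodel A [behavior_model()].
#' @param seed Master seed; per-session streams are derived by fixed
#'   offsets.
#' @param eeg If `TRUE`, synthesize an EEG recording per session (costly).
#' @param eeg_sampling_rate,template Forwarded to [synthesize_eeg()].
#' @param out_dir If non-`NULL`, write events/behavior CSVs and per-session
#'   hypnogram CSVs (and EDFs when `eeg = TRUE`) into this directory.
#' @return A list: `events` (data.frame), `behavior` (data.frame),
#'   `sessions` (list of per-session lists with `subject_id`, `condition`,
#'   `dose`, `severity`, `hypnogram`, and `eeg` when requested), `design`.
#' @export
simulate_cohort <- function(design, params = sleep_architecture_params(),
                            bmodel = behavior_model(), seed = 1,
                            eeg = FALSE, eeg_sampling_rate = 250,
                            template = spectral_template(), out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  k <- length(design$doses)
  cond_names <- ifelse(design$doses == 0, "vehicle",
                       paste0(design$compound, "_", design$doses))
  noxious <- design$compound == "lactic_acid"

  events <- list(); behavior <- list(); sessions <- list()
  for (i in seq_len(design$n_subjects)) {
    sid <- sprintf("rat%02d", i)
    order_row <- design$latin_square[((i - 1L) %% nrow(design$latin_square)) + 1L, ]
    for (pos in seq_len(k)) {
      j <- order_row[pos]
      dose <- design$doses[j]
      sseed <- seed + 1013L * i + 97L * j
      sev <- with_preserved_seed(sseed + 7L,
                                 stats::rnorm(1, 0, bmodel$severity_sd))

      ivs <- intervention_preset(design$compound, dose, design$dosing_zt)
      if (noxious && dose > 0) {
        sc <- exp(bmodel$severity_sleep * sev)
        ivs[[1L]]$wake_propensity_mult <- ivs[[1L]]$wake_propensity_mult * sc
        ivs[[1L]]$nrem_bout_mult <- ivs[[1L]]$nrem_bout_mult / sc
        ivs[[1L]]$latency_delay_min <- ivs[[1L]]$latency_delay_min * sc
      }
      h <- simulate_hypnogram(params, ivs, hours = design$hours, seed = sseed)

      lam <- bmodel$base_rates
      if (noxious) {
        lam <- lam * exp(bmodel$conc_slopes * dose)
        if (dose > 0) {
          lam["stretching"] <- lam["stretching"] *
            exp(bmodel$severity_behavior * sev)
        }
      }
      counts <- with_preserved_seed(sseed + 13L,
                                    stats::rpois(3, lam))

      events[[length(events) + 1L]] <- data.frame(
        subject_id = sid, zt_time = design$dosing_zt,
        compound = design$compound, dose = dose,
        unit = if (noxious) "pct" else "mg/kg", route = "i.p.",
        condition = cond_names[j], session = pos,
        stringsAsFactors = FALSE)
      behavior[[length(behavior) + 1L]] <- data.frame(
        subject_id = sid, condition = cond_names[j], window_min = 30,
        stretching = counts[1L], rearing = counts[2L], grooming = counts[3L],
        stringsAsFactors = FALSE)
      ses <- list(subject_id = sid, condition = cond_names[j], dose = dose,
                  severity = sev, hypnogram = h)
      if (isTRUE(eeg)) {
        ses$eeg <- synthesize_eeg(h, template,
                                  sampling_rate = eeg_sampling_rate,
                                  seed = sseed + 29L)
      }
      sessions[[paste(sid, cond_names[j], sep = "_")]] <- ses
    }
  }
  events <- do.call(rbind, events)
  behavior <- do.call(rbind, behavior)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(events[, c("subject_id", "zt_time", "compound", "dose",
                                "unit", "route")],
                     file.path(out_dir, "events.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(behavior, file.path(out_dir, "behavior.csv"),
                     row.names = FALSE, quote = FALSE)
    for (nm in names(sessions)) {
      write_hypnogram(sessions[[nm]]$hypnogram,
                      file.path(out_dir, paste0(nm, "_hypnogram.csv")))
      if (!is.null(sessions[[nm]]$eeg)) {
        write_edf(sessions[[nm]]$eeg, file.path(out_dir, paste0(nm, ".edf")))
      }
    }
  }
  list(events = events, behavior = behavior, sessions = sessions,
       design = design)
}
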