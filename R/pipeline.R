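# End-to-end orchestration: simulate or ingest -> hypnogram metrics -> qEEG
# -> dose-response statistics, with a JSON manifest capturing config, seeds
# and row counts. Outputs are deterministic given config + seed.

PIPELINE_KEYS <- c("seed", "out_dir", "simulate", "inputs", "bins_h",
                   "bout_window_h", "rules", "qeeg", "stats")

validate_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$out_dir)) stop("config requires out_dir")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config requires either 'simulate' or 'inputs'")
  }
  if (!is.null(config$inputs)) {
    for (p in unlist(config$inputs)) {
      if (!file.exists(p)) stop(sprintf("input not found before any stage ran: '%s'", p))
    }
  }
  invisible(config)
}

#' Group mean and SEM per condition and time bin
#'
#' @param metrics A metrics `data.frame` (e.g. from [run_pipeline()] or
#'   rbind-ed [sleep_metrics()] rows).
#' @param value_col Metric column to summarize.
#' @param by Grouping columns (default condition and bin end).
#' @return A `data.frame` with the grouping columns, `mean`, `sem`, `n`.
#'   Groups of a single subject report `sem = NA` (logged).
#' @export
summarize_timecourse <- function(metrics, value_col = "nrem_min",
                                 by = c("condition", "bin_end")) {
  if (!value_col %in% names(metrics)) {
    stop(sprintf("column '%s' not in metrics", value_col))
  }
  v <- metrics[[value_col]]
  ok <- !is.na(v)
  key <- interaction(metrics[by], drop = TRUE)
  agg <- data.frame(unique(metrics[ok, by, drop = FALSE]))
  key_u <- interaction(agg[by], drop = TRUE)
  mean_ <- tapply(v[ok], key[ok], mean)
  n_ <- tapply(v[ok], key[ok], length)
  sd_ <- tapply(v[ok], key[ok], stats::sd)
  m <- match(as.character(key_u), names(mean_))
  agg$mean <- as.numeric(mean_[m])
  agg$n <- as.integer(n_[m])
  agg$sem <- as.numeric(sd_[m]) / sqrt(agg$n)
  if (any(agg$n == 1L)) {
    message(sprintf("%d group(s) have a single subject; SEM is NA", sum(agg$n == 1L)))
    agg$sem[agg$n == 1L] <- NA_real_
  }
  rownames(agg) <- NULL
  agg[order(key_u), , drop = FALSE]
}

# condition levels in dose order, vehicle first
condition_levels <- function(events) {
  u <- unique(events[, c("condition", "dose")])
  u$condition[order(u$dose)]
}

#' Run the full analysis pipeline
#'
#' Stages, in order: acquire data (simulate a cohort, or ingest hypnogram /
#' event files), hypnogram metrics, optional state-conditioned qEEG, and
#' repeated-measures statistics on a chosen metric. Writes `metrics.tsv`,
#' `stats.tsv`, optionally `qeeg.tsv`, and `manifest.json` into
#' `config$out_dir`. Any stage failure removes that stage's partial outputs
#' and aborts with an error naming the stage.
#'
#' Config keys: `seed`; `out_dir`; `simulate` (list passed to
#' [experiment_design()]) or `inputs` (list with `events` CSV and
#' `hypnogram_dir` of `<subject>_<condition>_hypnogram.csv` files); `bins_h`
#' (default `c(1, 3, 6)`); `bout_window_h` (default 3); `rules`
#' ([scoring_rules()] arguments); `qeeg` (list: `enabled`, `sampling_rate`,
#' `bin_h`, `baseline_zt`); `stats` (list: `metric`, `bin_h`, `control`).
#' Unknown keys are rejected by name.
#'
#' @param config A named list, or the path to a YAML file of the same shape.
#' @return Invisibly, a list with `metrics`, `qeeg`, `stats`, `manifest`,
#'   and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bins_h <- if (is.null(config$bins_h)) c(1, 3, 6) else as.numeric(config$bins_h)
  bout_window_h <- if (is.null(config$bout_window_h)) 3 else config$bout_window_h
  rules <- if (is.null(config$rules)) scoring_rules() else
    do.call(scoring_rules, config$rules)
  qeeg_cfg <- utils::modifyList(
    list(enabled = FALSE, sampling_rate = 250, bin_h = 1,
         baseline_zt = c(0, 2)),
    if (is.null(config$qeeg)) list() else config$qeeg)
  stats_cfg <- utils::modifyList(
    list(metric = "nrem_min", bin_h = 3, control = "vehicle"),
    if (is.null(config$stats)) list() else config$stats)

  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- stage: data ----
  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      des <- do.call(experiment_design, config$simulate)
      simulate_cohort(des, seed = seed, eeg = isTRUE(qeeg_cfg$enabled),
                      eeg_sampling_rate = qeeg_cfg$sampling_rate)
    } else {
      ev <- read_events(config$inputs$events)
      ev$condition <- ifelse(ev$dose == 0, "vehicle",
                             paste0(ev$compound, "_", ev$dose))
      sess <- list()
      for (r in seq_len(nrow(ev))) {
        nm <- paste(ev$subject_id[r], ev$condition[r], sep = "_")
        path <- file.path(config$inputs$hypnogram_dir,
                          paste0(nm, "_hypnogram.csv"))
        if (!file.exists(path)) stop(sprintf("hypnogram not found: '%s'", path))
        sess[[nm]] <- list(subject_id = ev$subject_id[r],
                           condition = ev$condition[r], dose = ev$dose[r],
                           hypnogram = read_hypnogram(path))
      }
      list(events = ev, sessions = sess, behavior = NULL)
    }
  })

  # ---- stage: metrics ----
  metrics <- stage("metrics", {
    rows <- lapply(dat$sessions, function(s) {
      t0 <- dat$events$zt_time[dat$events$subject_id == s$subject_id &
                                 dat$events$condition == s$condition][1L]
      sleep_metrics(s$hypnogram, t0_zt = t0, bins_h = bins_h,
                    bout_window_h = bout_window_h, rules = rules,
                    subject_id = s$subject_id, condition = s$condition)
    })
    m <- do.call(rbind, c(rows, make.row.names = FALSE))
    p <- file.path(out_dir, "metrics.tsv")
    write_metrics_table(m, p)
    written <- c(written, p)
    m
  })

  # ---- stage: qeeg ----
  qeeg_tab <- NULL
  if (isTRUE(qeeg_cfg$enabled)) {
    qeeg_tab <- stage("qeeg", {
      rows <- lapply(dat$sessions, function(s) {
        if (is.null(s$eeg)) stop("qEEG enabled but session has no EEG signal")
        psd <- epoch_psd(s$eeg, s$hypnogram)
        hours <- length(s$hypnogram$labels) * s$hypnogram$epoch_length / 3600
        edges <- seq(s$hypnogram$start_zt, s$hypnogram$start_zt + hours,
                     by = qeeg_cfg$bin_h)
        tc <- state_band_timecourse(psd, s$hypnogram,
                                    bin_edges_zt = edges,
                                    subject_id = s$subject_id)
        tc$condition <- s$condition
        baseline_normalize(tc, as.numeric(qeeg_cfg$baseline_zt))
      })
      q <- do.call(rbind, c(rows, make.row.names = FALSE))
      p <- file.path(out_dir, "qeeg.tsv")
      write_metrics_table(q, p)
      written <- c(written, p)
      q
    })
  }

  # ---- stage: stats ----
  stats_tab <- stage("stats", {
    sel <- metrics[abs(metrics$bin_end - metrics$bin_start - stats_cfg$bin_h) < 1e-9, ]
    if (nrow(sel) == 0L) stop(sprintf("no metrics bin of width %g h", stats_cfg$bin_h))
    levs <- condition_levels(dat$events)
    subs <- unique(sel$subject_id)
    Y <- matrix(NA_real_, length(subs), length(levs),
                dimnames = list(subs, levs))
    for (r in seq_len(nrow(sel))) {
      Y[sel$subject_id[r], sel$condition[r]] <- sel[[stats_cfg$metric]][r]
    }
    an <- rm_anova_oneway(rm_design(Y, control = stats_cfg$control),
                          dunnett = TRUE, seed = seed)
    omni <- data.frame(test = "rm_anova", metric = stats_cfg$metric,
                       term = "condition", estimate = NA_real_,
                       statistic = an$f_stat, df1 = an$df_num,
                       df2 = an$df_den, epsilon = an$epsilon,
                       p = an$p_value, p_adj = NA_real_, seed = seed,
                       stringsAsFactors = FALSE)
    dn <- data.frame(test = "dunnett", metric = stats_cfg$metric,
                     term = an$dunnett$condition,
                     estimate = an$dunnett$estimate,
                     statistic = an$dunnett$t, df1 = an$dunnett$df,
                     df2 = NA_real_, epsilon = NA_real_,
                     p = an$dunnett$p_raw, p_adj = an$dunnett$p_adj,
                     seed = seed, stringsAsFactors = FALSE)
    s <- rbind(omni, dn)
    p <- file.path(out_dir, "stats.tsv")
    write_metrics_table(s, p)
    written <- c(written, p)
    s
  })

  # ---- stage: manifest ----
  manifest <- stage("manifest", {
    man <- list(
      manifest_id = substr(tools::md5sum(file.path(out_dir, "metrics.tsv")), 1, 12),
      package_version = as.character(utils::packageVersion("somnoscore")),
      seed = seed,
      config = config,
      outputs = lapply(stats::setNames(nm = basename(written)), function(b) {
        p <- file.path(out_dir, b)
        list(md5 = unname(tools::md5sum(p)),
             rows = length(readLines(p)) - 1L)
      }))
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(man, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, p)
    man
  })

  invisible(list(metrics = metrics, qeeg = qeeg_tab, stats = stats_tab,
                 manifest = manifest, paths = written))
}
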