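# Delimited-text I/O for hypnograms, dosing events, behavior counts and
# metric tables. Readers validate strictly and fail with row numbers rather
# than coerce; silent coercion corrupts duration sums downstream.

LABEL_DIALECTS <- c(
  "W" = "WAKE", "WAKE" = "WAKE",
  "N" = "NREM", "NREM" = "NREM",
  "R" = "REM",  "REM" = "REM",
  "A" = "ARTIFACT", "ART" = "ARTIFACT", "ARTIFACT" = "ARTIFACT"
)

#' Read a hypnogram from delimited text
#'
#' Expects a CSV with header `epoch_index,label`, one epoch per row. Labels
#' are mapped case-insensitively from the dialects `W`/`WAKE`, `N`/`NREM`,
#' `R`/`REM`, `A`/`ART`/`ARTIFACT`; anything else is an error naming the row.
#' Epoch indices must be contiguous.
#'
#' @param path Path to the CSV file.
#' @param epoch_length Epoch length in seconds (default 10).
#' @param start_zt ZT hours of the first epoch (default 0).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = 10, start_zt = 0) {
  if (!file.exists(path)) stop(sprintf("hypnogram file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(df), c("epoch_index", "label"))) {
    stop(sprintf("hypnogram '%s' must have header 'epoch_index,label' (got '%s')",
                 path, paste(names(df), collapse = ",")))
  }
  if (nrow(df) == 0L) stop(sprintf("hypnogram '%s' has no epochs", path))
  idx <- suppressWarnings(as.integer(df$epoch_index))
  if (anyNA(idx)) {
    stop(sprintf("non-integer epoch_index at row %d of '%s'",
                 which(is.na(idx))[1L], path))
  }
  if (any(diff(idx) != 1L)) {
    stop(sprintf("non-contiguous epoch_index at row %d of '%s'",
                 which(diff(idx) != 1L)[1L] + 1L, path))
  }
  key <- toupper(df$label)
  mapped <- LABEL_DIALECTS[key]
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1L]
    stop(sprintf("unknown stage label '%s' at row %d of '%s'",
                 df$label[bad], bad, path))
  }
  hypnogram(unname(mapped), epoch_length = epoch_length, start_zt = start_zt)
}

#' Write a hypnogram to delimited text
#'
#' Inverse of [read_hypnogram()]: header `epoch_index,label`, zero-based
#' contiguous indices, canonical labels.
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(h$labels) - 1L, label = h$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dosing-events table
#'
#' CSV with header `subject_id,zt_time,compound,dose,unit,route`. ZT times
#' must lie in `[0, 24)`; doses must be non-negative.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with those columns (`zt_time`, `dose` numeric).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("events file not found: '%s'", path))
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("subject_id", "zt_time", "compound", "dose", "unit", "route")
  if (!identical(names(df), need)) {
    stop(sprintf("events file '%s' must have header '%s'",
                 path, paste(need, collapse = ",")))
  }
  df$zt_time <- as.numeric(df$zt_time)
  df$dose <- as.numeric(df$dose)
  if (anyNA(df$zt_time) || any(df$zt_time < 0 | df$zt_time >= 24)) {
    bad <- which(is.na(df$zt_time) | df$zt_time < 0 | df$zt_time >= 24)[1L]
    stop(sprintf("zt_time out of [0, 24) at row %d of '%s'", bad, path))
  }
  if (anyNA(df$dose) || any(df$dose < 0)) {
    bad <- which(is.na(df$dose) | df$dose < 0)[1L]
    stop(sprintf("negative or non-numeric dose at row %d of '%s'", bad, path))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read a behavior-count table
#'
#' CSV with header `subject_id,condition,window_min,stretching,rearing,grooming`.
#' Counts must be non-negative integers; the observation window (minutes)
#' positive.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with those columns.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop(sprintf("behavior file not found: '%s'", path))
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("subject_id", "condition", "window_min",
            "stretching", "rearing", "grooming")
  if (!identical(names(df), need)) {
    stop(sprintf("behavior file '%s' must have header '%s'",
                 path, paste(need, collapse = ",")))
  }
  df$window_min <- as.numeric(df$window_min)
  if (anyNA(df$window_min) || any(df$window_min <= 0)) {
    stop(sprintf("non-positive window_min in '%s'", path))
  }
  for (col in c("stretching", "rearing", "grooming")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(v < 0) || any(v != round(v))) {
      bad <- which(is.na(v) | v < 0 | v != round(v))[1L]
      stop(sprintf("%s count at row %d of '%s' is not a non-negative integer",
                   col, bad, path))
    }
    df[[col]] <- as.integer(v)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write a metrics table as TSV
#'
#' Tab-separated output with a deterministic column order (the input order)
#' and fixed-precision numeric serialization, so identical tables produce
#' byte-identical files.
#'
#' @param table A `data.frame`, or a list of named rows sharing one schema.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path, digits = 6) {
  if (is.list(table) && !is.data.frame(table)) {
    if (length(table) > 0L) {
      schemas <- lapply(table, names)
      if (any(!vapply(schemas, identical, logical(1), schemas[[1L]]))) {
        bad <- which(!vapply(schemas, identical, logical(1), schemas[[1L]]))[1L]
        stop(sprintf("mixed-schema rows: row %d does not match row 1", bad))
      }
    }
    table <- do.call(rbind, lapply(table, function(r) as.data.frame(r)))
  }
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- formatC(out[[j]], format = "f", digits = digits)
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics TSV written by [write_metrics_table()]
#' @param path Path to the TSV file.
#' @return A `data.frame`.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("metrics file not found: '%s'", path))
  utils::read.delim(path, check.names = FALSE)
}
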