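# Minimal European Data Format (EDF) support: 16-bit signals, fixed-layout
# ASCII header of 256 + 256*ns bytes, little-endian integer data records.
# Covers exactly what the pipeline needs (single-species polysomnography
# exports); EDF+ annotations are out of scope.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop(sprintf("EDF header field too wide: '%s'", s))
  formatC(s, width = width, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' Emits a single-channel EDF with one-second data records. Samples are
#' quantized to 16-bit integers over a symmetric physical range covering the
#' data, so the round-trip error is at most one quantization step of that
#' range.
#'
#' @param recording An [eeg_recording()]. The sample count must be a whole
#'   number of seconds at the sampling rate.
#' @param path Output file path.
#' @param physical_unit Unit string written to the header (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_unit = "uV") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- length(recording$samples)
  if (n %% fs != 0L) {
    stop("sample count must be a whole number of seconds at the sampling rate")
  }
  n_rec <- n %/% fs

  # symmetric physical range covering the data, rounded UP to 2 significant
  # digits so it always fits the 8-character header field and never clips
  pmax_ <- max(abs(recording$samples))
  if (pmax_ == 0) pmax_ <- 1
  pmax_ <- signif(pmax_ * 1.06, 2)
  dig_min <- -32767L; dig_max <- 32767L
  digital <- as.integer(round(recording$samples / pmax_ * dig_max))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),                      # version
    edf_field("synthetic subject", 80),     # patient id
    edf_field("somnoscore export", 80),     # recording id
    edf_field("01.01.00", 8),               # start date (ZT anchoring is sidecar)
    edf_field("00.00.00", 8),               # start time
    edf_field(256 + 256, 8),                # header bytes (1 signal)
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),                      # record duration (s)
    edf_field("1", 4)                       # number of signals
  )
  sig <- paste0(
    edf_field(recording$channel_label, 16),
    edf_field("", 80),                      # transducer
    edf_field(physical_unit, 8),
    edf_field(formatC(-pmax_, format = "g"), 8),
    edf_field(formatC(pmax_, format = "g"), 8),
    edf_field(dig_min, 8),
    edf_field(dig_max, 8),
    edf_field("", 80),                      # prefiltering
    edf_field(fs, 8),                       # samples per record
    edf_field("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_header <- function(con, path) {
  raw_hdr <- readBin(con, "raw", 256L)
  if (length(raw_hdr) < 256L) {
    stop(sprintf("EDF format error in '%s': truncated header at byte %d",
                 path, length(raw_hdr)))
  }
  txt <- rawToChar(raw_hdr)
  fld <- function(from, width) trimws(substr(txt, from, from + width - 1L))
  ns <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(ns) || ns < 1L) {
    stop(sprintf("EDF format error in '%s': file declares %s signals",
                 path, fld(253, 4)))
  }
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  hdr_bytes <- suppressWarnings(as.integer(fld(185, 8)))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(hdr_bytes)) {
    stop(sprintf("EDF format error in '%s': malformed header fields", path))
  }

  sig_raw <- readBin(con, "raw", 256L * ns)
  if (length(sig_raw) < 256L * ns) {
    stop(sprintf("EDF format error in '%s': truncated signal header at byte %d",
                 path, 256L + length(sig_raw)))
  }
  sig_txt <- rawToChar(sig_raw)
  # signal headers are stored field-by-field across all signals
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      from <- offset + (i - 1L) * width + 1L
      trimws(substr(sig_txt, from, from + width - 1L))
    }, character(1))
  }
  pos <- 0L
  labels <- grab(pos, 16L); pos <- pos + ns * 16L
  pos <- pos + ns * 80L                                  # transducer
  units <- grab(pos, 8L); pos <- pos + ns * 8L
  phys_min <- as.numeric(grab(pos, 8L)); pos <- pos + ns * 8L
  phys_max <- as.numeric(grab(pos, 8L)); pos <- pos + ns * 8L
  dig_min <- as.numeric(grab(pos, 8L)); pos <- pos + ns * 8L
  dig_max <- as.numeric(grab(pos, 8L)); pos <- pos + ns * 8L
  pos <- pos + ns * 80L                                  # prefiltering
  spr <- as.integer(grab(pos, 8L))
  list(ns = ns, n_rec = n_rec, rec_dur = rec_dur, hdr_bytes = hdr_bytes,
       labels = labels, units = units, phys_min = phys_min,
       phys_max = phys_max, dig_min = dig_min, dig_max = dig_max, spr = spr)
}

#' Read one channel of an EDF file
#'
#' @param path Path to an EDF file.
#' @param channel Channel label to extract; `NULL` (default) takes the first
#'   channel.
#' @param start_zt ZT hours of the recording start. EDF clocks carry wall
#'   time, not Zeitgeber time, so the ZT anchor is supplied here (sidecar
#'   metadata), not read from the file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel = NULL, start_zt = 0) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con, path)

  idx <- if (is.null(channel)) 1L else match(channel, h$labels)
  if (is.na(idx)) {
    stop(sprintf("EDF format error in '%s': channel '%s' not present (have: %s)",
                 path, channel, paste(h$labels, collapse = ", ")))
  }

  samples_per_record <- sum(h$spr)
  expect_bytes <- h$hdr_bytes + 2 * samples_per_record * h$n_rec
  actual <- file.size(path)
  if (actual < expect_bytes) {
    stop(sprintf("EDF format error in '%s': truncated record data at byte %d (expected %d bytes)",
                 path, actual, expect_bytes))
  }

  data <- readBin(con, "integer", samples_per_record * h$n_rec, size = 2L,
                  signed = TRUE, endian = "little")
  data <- matrix(data, nrow = samples_per_record)
  offs <- c(0L, cumsum(h$spr))
  rows <- (offs[idx] + 1L):offs[idx + 1L]
  digital <- as.numeric(data[rows, , drop = FALSE])

  scale <- (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
  physical <- (digital - h$dig_min[idx]) * scale + h$phys_min[idx]
  eeg_recording(physical, sampling_rate = h$spr[idx] / h$rec_dur,
                start_zt = start_zt, channel_label = h$labels[idx])
}

#' Quantization step of an EDF channel
#'
#' One digital unit expressed in physical units; the worst-case round-trip
#' error of [write_edf()] followed by [read_edf()].
#'
#' @param path Path to an EDF file.
#' @param channel Channel label (`NULL`: first channel).
#' @return Physical value of one quantization step.
#' @export
edf_quantization_step <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con, path)
  idx <- if (is.null(channel)) 1L else match(channel, h$labels)
  if (is.na(idx)) stop(sprintf("channel '%s' not present", channel))
  (h$phys_max[idx] - h$phys_min[idx]) / (h$dig_max[idx] - h$dig_min[idx])
}
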