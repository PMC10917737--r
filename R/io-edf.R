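#' Read an EDF (European Data Format) recording
#'
#' Minimal reader for standard EDF polysomnography files: fixed-width ASCII
#' header, per-signal headers, then data records of 16-bit little-endian
#' integers which are mapped to physical units through each signal's
#' digital/physical calibration range.  Only the requested channels are
#' decoded; matching is case-insensitive and tolerant of separator variants
#' (`"F4-A1"`/`"F4_A1"`/`"F4A1"`).
#'
#' @param path EDF file path.
#' @param wanted_channels channel labels to extract, in the desired order.
#'   `NULL` extracts every signal.
#' @param subject_id,group_label metadata attached to the returned
#'   recording; `subject_id = NULL` uses the file's local patient field.
#' @return An [eeg_recording()] whose `fs` is taken from the file.  Mixed
#'   sampling rates among the selected channels are rejected.
#' @export
read_edf <- function(path, wanted_channels = NULL, subject_id = NULL,
                     group_label = "UNKNOWN") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  patient <- field(hdr, 9, 80)
  n_records <- as.integer(field(hdr, 237, 8))
  record_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1) abort("Invalid EDF: bad signal count in header.")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  grab <- function(offset, len) {
    vapply(seq_len(ns) - 1L, function(i) {
      field(sig_hdr, offset * ns + i * len + 1, len)
    }, character(1))
  }
  labels <- grab(0, 16)
  phys_min <- as.numeric(grab(16 + 80 + 8, 8))
  phys_max <- as.numeric(grab(16 + 80 + 8 + 8, 8))
  dig_min <- as.numeric(grab(16 + 80 + 8 + 8 + 8, 8))
  dig_max <- as.numeric(grab(16 + 80 + 8 + 8 + 8 + 8, 8))
  spr <- as.integer(grab(16 + 80 + 8 + 8 + 8 + 8 + 8 + 80, 8))

  idx <- if (is.null(wanted_channels)) seq_len(ns) else {
    match_channels(labels, wanted_channels)
  }
  fs_sel <- spr[idx] / record_dur
  if (length(unique(fs_sel)) != 1) {
    abort(sprintf(
      "Mixed sampling rates among selected channels: %s",
      paste(sprintf("%s=%g Hz", labels[idx], fs_sel), collapse = ", ")
    ))
  }

  raw_rec <- readBin(con, "integer", n = sum(spr) * n_records, size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_rec) < sum(spr) * n_records) {
    abort("Truncated EDF: fewer data samples than the header declares.")
  }
  # offsets of each signal's block inside one record
  off <- c(0, cumsum(spr))
  out <- lapply(idx, function(j) {
    pick <- as.vector(outer(off[j] + seq_len(spr[j]),
                            (seq_len(n_records) - 1L) * sum(spr), `+`))
    dig <- raw_rec[pick]
    scale <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    phys_min[j] + (dig - dig_min[j]) * scale
  })
  mat <- do.call(rbind, out)
  eeg_recording(mat, labels[idx], fs_sel[1],
                subject_id = subject_id %||%
                  (if (nzchar(patient)) patient else "subject"),
                group_label = group_label)
}

#' Write a recording as an EDF fixture
#'
#' Companion writer used to build test fixtures and to materialize
#' synthetic cohorts in a format real tooling can open.  Signals are scaled
#' to the full 16-bit digital range of their per-channel physical extremes,
#' so the round trip is exact up to that quantization step.
#'
#' @param rec an [eeg_recording()]; `fs` must be a positive integer so
#'   that 1-second data records hold a whole number of samples.
#' @param path output path.
#' @return `path`, invisibly.  Trailing samples that do not fill a whole
#'   1-s record are dropped (EDF stores complete records only).
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) abort("write_edf needs an integer sampling rate.")
  ns <- nrow(rec$data)
  n_records <- ncol(rec$data) %/% fs
  if (n_records < 1) abort("Recording shorter than one 1-s EDF record.")
  dat <- rec$data[, seq_len(n_records * fs), drop = FALSE]

  # physical range rounded UP to 2 significant digits: the 8-char ASCII
  # header field then carries it exactly (reader and writer share one
  # affine map) and no sample can overflow the digital range
  sig_ceil <- function(x) {
    e <- floor(log10(x)) - 1
    ceiling(x / 10^e) * 10^e
  }
  pmax_ <- apply(abs(dat), 1, max)
  pmax_ <- vapply(ifelse(pmax_ > 0, pmax_ * 1.001, 1), sig_ceil, numeric(1))
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) {
    x <- as.character(x)
    if (any(nchar(x) > w)) abort("EDF header field overflow.")
    formatC(x, width = w, flag = "-")
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 7), w)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad("osaconnect fixture", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_records, 8), pad(1, 8), pad(ns, 4)
  )
  shdr <- paste0(
    paste(pad(rec$channel_labels, 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(num(-pmax_, 8), collapse = ""),
    paste(num(pmax_, 8), collapse = ""),
    paste(num(rep(dmin, ns), 8), collapse = ""),
    paste(num(rep(dmax, ns), 8), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(num(rep(fs, ns), 8), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, shdr), con, eos = NULL)

  # physical -> digital with the same affine map the reader inverts
  dig <- matrix(0L, ns, ncol(dat))
  for (j in seq_len(ns)) {
    scale <- (dmax - dmin) / (2 * pmax_[j])
    dig[j, ] <- as.integer(pmin(pmax(
      round(dmin + (dat[j, ] + pmax_[j]) * scale), dmin), dmax))
  }
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
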