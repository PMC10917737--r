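#' Build a multichannel EEG recording
#'
#' The basic unit of ingestion and synthesis: a channels-by-samples numeric
#' matrix with channel labels, a sampling rate, a subject identifier and a
#' group label.  All readers and the synthetic generator return this class;
#' every downstream stage (filtering, wavelet decomposition, connectivity)
#' consumes it.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param channel_labels character vector, one unique label per row of
#'   `data`.  Sleep-EEG derivations such as `"F4-A1"` are labels only; the
#'   signals are assumed already referenced.
#' @param fs sampling rate in Hz (positive scalar).
#' @param subject_id subject identifier string.
#' @param group_label one of `"OSA"`, `"HEALTHY"`, `"UNKNOWN"`.
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 2), c("F3-A2", "F4-A1"), fs = 200)
#' rec
#' @export
eeg_recording <- function(data, channel_labels, fs, subject_id = "subject",
                          group_label = c("UNKNOWN", "OSA", "HEALTHY")) {
  group_label <- match.arg(toupper(group_label[1]), c("UNKNOWN", "OSA", "HEALTHY"))
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (length(channel_labels) != nrow(data)) {
    abort("One channel label per row of `data` is required.")
  }
  if (anyDuplicated(channel_labels)) {
    abort("Channel labels must be unique.")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive scalar (Hz).")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort("Recording contains NaN/Inf samples; repair or reject upstream.")
  }
  dimnames(data) <- list(channel_labels, NULL)
  structure(
    list(
      channel_labels = as.character(channel_labels),
      fs = as.numeric(fs),
      data = data,
      subject_id = as.character(subject_id),
      group_label = group_label
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s [%s]  %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group_label, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs
  ))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Recording as a long tibble
#'
#' One row per (channel, sample), with time in seconds; convenient for
#' ggplot2 and dplyr workflows.
#'
#' @param x an [eeg_recording()].
#' @param ... unused.
#' @return A tibble with columns `subject_id`, `channel`, `time`, `value`.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble(
    subject_id = x$subject_id,
    channel = rep(x$channel_labels, each = n),
    time = rep(seq_len(n) - 1, times = nrow(x$data)) / x$fs,
    value = as.vector(t(x$data))
  )
}

# Canonical form used for tolerant channel matching: case and separator
# variants ("F4-A1" / "F4_A1" / "f4a1") compare equal.
normalize_label <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

match_channels <- function(available, wanted) {
  idx <- match(normalize_label(wanted), normalize_label(available))
  if (anyNA(idx)) {
    abort(sprintf(
      "Channel(s) not found: %s. Available channels: %s",
      paste(wanted[is.na(idx)], collapse = ", "),
      paste(available, collapse = ", ")
    ))
  }
  idx
}

#' Select channels from a recording
#'
#' @param rec an [eeg_recording()].
#' @param channels labels to keep, in the requested order.  Matching is
#'   case-insensitive and tolerant of separator variants
#'   (`"F4-A1"`/`"F4_A1"`/`"F4A1"`).
#' @return An `eeg_recording` with exactly the requested channels.
#' @export
select_channels <- function(rec, channels) {
  idx <- match_channels(rec$channel_labels, channels)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$channel_labels[idx],
                rec$fs, rec$subject_id, rec$group_label)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Sleep recordings are conventionally analysed in 30-s epochs; trailing
#' samples that do not fill a whole epoch are discarded, so concatenating
#' the returned epochs reproduces the truncated recording exactly.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_seconds epoch length in seconds (default 30, the standard
#'   polysomnography epoch).
#' @return A list of `eeg_epoch` objects, each holding a channels x
#'   (fs * epoch_seconds) matrix plus the parent `subject_id` and a 0-based
#'   `index`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 13000), 2), c("a", "b"), fs = 200)
#' length(make_epochs(rec, 30))  # 2 epochs, 5 s discarded
#' @export
make_epochs <- function(rec, epoch_seconds = 30) {
  stopifnot(is.numeric(epoch_seconds), epoch_seconds > 0)
  len <- as.integer(round(rec$fs * epoch_seconds))
  n <- ncol(rec$data)
  k <- n %/% len
  if (k < 1) {
    abort(sprintf(
      "Recording too short: %d samples < one %g-s epoch (%d samples).",
      n, epoch_seconds, len
    ))
  }
  lapply(seq_len(k) - 1L, function(i) {
    structure(
      list(
        subject_id = rec$subject_id,
        index = i,
        fs = rec$fs,
        channel_labels = rec$channel_labels,
        data = rec$data[, (i * len + 1):((i + 1) * len), drop = FALSE]
      ),
      class = "eeg_epoch"
    )
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s #%d  %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$index, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
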