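#' Read and write the columnar text fixture format
#'
#' A plain-text interchange format for small signals: comment lines carry
#' metadata (`# fs=<Hz>` is mandatory; `# subject_id=` and `# group=` are
#' optional), a single header row names the channels, and each subsequent
#' row holds one sample per channel (tab-separated).  The round trip is
#' lossless at full double precision.
#'
#' @param path file path.
#' @return [read_columnar()] returns an [eeg_recording()];
#'   [write_columnar()] returns `path` invisibly.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(20), 2), c("F3-A2", "F4-A1"), fs = 200)
#' f <- tempfile(fileext = ".tsv")
#' write_columnar(rec, f)
#' identical(read_columnar(f)$data, rec$data)
#' @export
read_columnar <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  meta <- list()
  for (m in meta_lines) {
    kv <- regmatches(m, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", m))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  if (is.null(meta$fs)) {
    abort("Missing metadata: columnar file must carry a '# fs=<Hz>' comment line.")
  }
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs)) abort(sprintf("Invalid fs metadata: '%s'", meta$fs))
  if (length(body) < 1) abort("Columnar file has no header row.")
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(labels))) {
    bad <- which(nfield != length(labels))[1]
    abort(sprintf(
      "Ragged row %d: %d values for a %d-channel table.",
      bad, nfield[bad], length(labels)
    ))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) abort("Non-numeric cell in columnar data.")
  mat <- matrix(vals, nrow = length(labels))  # row-major file -> channel rows
  eeg_recording(mat, labels, fs,
                subject_id = meta$subject_id %||% "subject",
                group_label = meta$group %||% "UNKNOWN")
}

#' @param rec an [eeg_recording()] to serialize.
#' @rdname read_columnar
#' @export
write_columnar <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", format(rec$fs, digits = 17)),
    sprintf("# subject_id=%s", rec$subject_id),
    sprintf("# group=%s", rec$group_label),
    paste(rec$channel_labels, collapse = "\t")
  ), con)
  # one sample per line, full precision
  writeLines(apply(rec$data, 2, function(col) {
    paste(format(col, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = "\t")
  }), con)
  invisible(path)
}
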