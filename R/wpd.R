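# Orthonormal Daubechies analysis filters (low-pass, analysis convention).
# 2p taps for p vanishing moments; the high-pass is the quadrature mirror.
.db_dec_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

wavelet_filters <- function(family) {
  family <- if (identical(family, "haar")) "db1" else family
  lo <- .db_dec_lo[[family]]
  if (is.null(lo)) {
    abort(sprintf("Unknown wavelet family '%s' (available: %s, haar).",
                  family, paste(names(.db_dec_lo), collapse = ", ")))
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L))
  list(lo = lo, hi = hi, length = L)
}

#' Wavelet-packet decomposition settings
#'
#' Defaults follow standard sleep-EEG practice: Daubechies-4 (8-tap)
#' wavelet, 5 decomposition levels, periodized boundary handling.  Level 5
#' at 200 Hz yields 32 leaves of 3.125 Hz each, enough to carve out the
#' five clinical bands.
#'
#' @param family wavelet family: `"db4"` (default), `"db2"`, `"db1"`/`"haar"`.
#' @param level decomposition depth (`2^level` leaves).
#' @param boundary boundary handling; only `"periodization"` is
#'   implemented (exact coefficient counts and an orthogonal transform).
#' @return A `wavelet_spec` list.
#' @export
wavelet_spec <- function(family = "db4", level = 5,
                         boundary = "periodization") {
  stopifnot(level >= 1)
  wavelet_filters(family)  # validates family
  if (!identical(boundary, "periodization")) {
    abort("Only the 'periodization' boundary mode is implemented.")
  }
  structure(list(family = family, level = as.integer(level),
                 boundary = boundary),
            class = "wavelet_spec")
}

# One periodized analysis split: x (even length) -> list(a, d).
wpd_split <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (m in seq_len(filt$length)) {
    xm <- x[(base + (m - 1L)) %% n + 1L]
    a <- a + filt$lo[m] * xm
    d <- d + filt$hi[m] * xm
  }
  list(a = a, d = d)
}

# Transpose (exact inverse) of wpd_split for the orthonormal filter pair.
wpd_merge <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  base <- 2L * (seq_len(half) - 1L)
  x <- numeric(n)
  for (m in seq_len(filt$length)) {
    pos <- (base + (m - 1L)) %% n + 1L
    x[pos] <- x[pos] + filt$lo[m] * a + filt$hi[m] * d
  }
  x
}

#' Wavelet packet decomposition of one signal
#'
#' Recursively splits both the approximation and the detail branch at
#' every level, yielding `2^level` equal-bandwidth leaves.  With the
#' periodized orthonormal filter bank the transform is exactly invertible
#' and energy preserving.  Signals whose length is not a multiple of
#' `2^level` are extended by repeating the last sample; the inverse
#' truncates back to the original length.
#'
#' @param x numeric vector, length at least `2^level`.
#' @param spec a [wavelet_spec()].
#' @return An `eeg_wpt` object: `leaves` (list of `2^level` coefficient
#'   vectors in natural filter-path order), `spec`, `n_samples`.
#' @seealso [wpd_reconstruct()], [frequency_order()], [extract_band()]
#' @export
wpd_decompose <- function(x, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  n <- length(x)
  block <- 2L^spec$level
  if (n < block) {
    abort(sprintf("Signal too short: %d samples < 2^%d leaves.", n, spec$level))
  }
  filt <- wavelet_filters(spec$family)
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) x <- c(x, rep(x[n], n_pad - n))
  nodes <- list(x)
  for (lev in seq_len(spec$level)) {
    nodes <- unlist(lapply(nodes, function(nd) {
      s <- wpd_split(nd, filt)
      list(s$a, s$d)
    }), recursive = FALSE)
  }
  structure(list(leaves = nodes, spec = spec, n_samples = n),
            class = "eeg_wpt")
}

#' @export
print.eeg_wpt <- function(x, ...) {
  cat(sprintf("<eeg_wpt> %s level %d: %d leaves x %d coefficients (n = %d)\n",
              x$spec$family, x$spec$level, length(x$leaves),
              length(x$leaves[[1]]), x$n_samples))
  invisible(x)
}

#' Inverse wavelet packet transform
#'
#' @param tree an `eeg_wpt` from [wpd_decompose()].
#' @param keep optional integer vector of natural-order leaf indices
#'   (0-based) to retain; all other leaves are zeroed before inversion.
#'   `NULL` keeps everything (perfect reconstruction).
#' @return Numeric vector of length `tree$n_samples`.
#' @export
wpd_reconstruct <- function(tree, keep = NULL) {
  stopifnot(inherits(tree, "eeg_wpt"))
  filt <- wavelet_filters(tree$spec$family)
  nodes <- tree$leaves
  if (!is.null(keep)) {
    drop <- setdiff(seq_along(nodes) - 1L, keep)
    for (i in drop) nodes[[i + 1L]] <- numeric(length(nodes[[i + 1L]]))
  }
  for (lev in seq_len(tree$spec$level)) {
    nodes <- lapply(seq_len(length(nodes) / 2L), function(i) {
      wpd_merge(nodes[[2L * i - 1L]], nodes[[2L * i]], filt)
    })
  }
  nodes[[1]][seq_len(tree$n_samples)]
}

#' Natural-order leaf index for each frequency position
#'
#' Wavelet-packet leaves indexed by filter path (low/high choices) are not
#' in ascending pass-band order: every high-pass-and-decimate stage
#' mirrors the spectrum, so spectral order is recovered by the binary
#' Gray code.
#'
#' @param level decomposition depth.
#' @return Integer vector of length `2^level`: element `p + 1` is the
#'   0-based natural-order index of the leaf whose pass-band is
#'   approximately `[p, p + 1] * fs / 2^(level + 1)`.
#' @examples
#' frequency_order(2)  # 0 1 3 2
#' @export
frequency_order <- function(level) {
  stopifnot(level >= 1)
  p <- 0:(2L^level - 1L)
  bitwXor(p, bitwShiftR(p, 1L))
}

#' Default clinical EEG band edges
#'
#' @return A tibble with columns `band`, `f_low`, `f_high` (Hz): delta
#'   0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-35 (gamma capped
#'   at the 35 Hz band-pass edge).
#' @export
eeg_bands <- function() {
  tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    f_low = c(0.5, 4, 8, 13, 30),
    f_high = c(4, 8, 13, 30, 35)
  )
}

check_bands <- function(bands) {
  stopifnot(all(c("band", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low >= bands$f_high)) abort("Band edges must satisfy f_low < f_high.")
  o <- order(bands$f_low)
  b <- bands[o, ]
  if (nrow(b) > 1 && any(b$f_low[-1] < b$f_high[-nrow(b)] - 1e-12)) {
    abort("Band definitions overlap.")
  }
  invisible(bands)
}

#' Assign wavelet-packet leaves to frequency bands
#'
#' Each leaf is a `fs / 2^(level + 1)`-wide slice of the spectrum
#' (3.125 Hz at 200 Hz, level 5); a leaf belongs to the band containing
#' its centre frequency (half-open `[f_low, f_high)` containment).  Leaves
#' whose centre lies in no band stay unassigned.
#'
#' @param fs sampling rate, Hz.
#' @param level decomposition depth.
#' @param bands a band table as from [eeg_bands()].
#' @return Named list mapping each band to the 0-based *frequency-ordered*
#'   leaf positions it owns (possibly empty).
#' @examples
#' band_leaf_map(200, 5)$delta  # leaf 0 (centre 1.5625 Hz)
#' band_leaf_map(200, 5)$beta   # leaves 4..9
#' @export
band_leaf_map <- function(fs, level, bands = eeg_bands()) {
  check_bands(bands)
  if (fs / 2 < max(bands$f_high)) {
    abort(sprintf("fs/2 = %g Hz below the highest band edge %g Hz.",
                  fs / 2, max(bands$f_high)))
  }
  width <- fs / 2 / 2^level
  centers <- (0:(2^level - 1) + 0.5) * width
  out <- lapply(seq_len(nrow(bands)), function(i) {
    which(centers >= bands$f_low[i] & centers < bands$f_high[i]) - 1L
  })
  names(out) <- as.character(bands$band)
  out
}

#' Extract one band's features from a packet tree
#'
#' The per-band feature used throughout the connectivity analysis is the
#' vector of absolute wavelet coefficients over the band's leaves
#' (ascending frequency order); the band-limited time series is obtained
#' by inverting the tree with all out-of-band leaves zeroed.
#'
#' @param tree an `eeg_wpt`.
#' @param band band name (must appear in `bands`).
#' @param fs sampling rate of the decomposed signal, Hz.
#' @param bands band table, default [eeg_bands()].
#' @param reconstruct also compute the band-limited signal?  Skipping it
#'   (`FALSE`) halves the cost when only `abs_coeffs` are needed.
#' @return A `band_features` list: `band`, `f_low`, `f_high`,
#'   `abs_coeffs`, `band_signal` (or `NULL`), `leaves` (0-based frequency
#'   positions used).
#' @export
extract_band <- function(tree, band, fs, bands = eeg_bands(),
                         reconstruct = TRUE) {
  stopifnot(inherits(tree, "eeg_wpt"))
  map <- band_leaf_map(fs, tree$spec$level, bands)
  if (!band %in% names(map)) {
    abort(sprintf("Unknown band '%s'.", band))
  }
  pos <- map[[band]]
  if (length(pos) == 0) {
    abort(sprintf(
      "Band '%s' owns no leaf at fs = %g Hz, level %d (leaf width %g Hz).",
      band, fs, tree$spec$level, fs / 2 / 2^tree$spec$level
    ))
  }
  nat <- frequency_order(tree$spec$level)[pos + 1L]
  row <- bands[as.character(bands$band) == band, ]
  structure(
    list(
      band = band, f_low = row$f_low, f_high = row$f_high,
      abs_coeffs = abs(unlist(tree$leaves[nat + 1L], use.names = FALSE)),
      band_signal = if (reconstruct) wpd_reconstruct(tree, keep = nat) else NULL,
      leaves = pos
    ),
    class = "band_features"
  )
}

#' Per-leaf energies of a packet tree
#'
#' @param x an `eeg_wpt`.
#' @param ... unused.
#' @return A tibble with one row per leaf: `leaf_natural` (0-based
#'   filter-path index), `leaf_freq_pos` (0-based spectral position),
#'   `energy`, `energy_frac`.
#' @export
tidy.eeg_wpt <- function(x, ...) {
  e <- vapply(x$leaves, function(v) sum(v^2), numeric(1))
  ord <- frequency_order(x$spec$level)
  tibble(
    leaf_natural = seq_along(e) - 1L,
    leaf_freq_pos = order(ord + 1L)[seq_along(e)] - 1L,
    energy = e,
    energy_frac = if (sum(e) > 0) e / sum(e) else e
  )
}
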