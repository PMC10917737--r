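#' Filter specification for sleep-EEG preprocessing
#'
#' Two cascaded stages remove power-line interference and restrict the
#' signal to the sleep-EEG band before wavelet decomposition: a
#' second-order IIR notch (default 50 Hz, quality factor 30) followed by a
#' Butterworth band-pass (default 0.5-35 Hz, order 4).  Both are applied
#' forward-backward, so the net filter has zero phase and squared
#' magnitude.
#'
#' @param notch_freq power-line frequency to remove, Hz.
#' @param notch_q dimensionless quality factor of the notch
#'   (centre frequency / -3 dB width).
#' @param band_low,band_high band-pass corner frequencies, Hz.
#' @param butter_order Butterworth prototype order (the band-pass doubles
#'   it, as usual).
#' @param zero_phase apply each filter forward and backward (no group
#'   delay)?  Default `TRUE`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30, band_low = 0.5,
                        band_high = 35, butter_order = 4, zero_phase = TRUE) {
  stopifnot(notch_freq > 0, notch_q > 0, butter_order >= 1)
  if (!(band_low > 0 && band_low < band_high)) {
    abort("Need 0 < band_low < band_high.")
  }
  structure(
    list(notch_freq = notch_freq, notch_q = notch_q, band_low = band_low,
         band_high = band_high, butter_order = as.integer(butter_order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

check_fs <- function(fs, spec) {
  if (spec$notch_freq >= fs / 2) {
    abort(sprintf("Sampling rate %g Hz too low for a %g Hz notch.",
                  fs, spec$notch_freq))
  }
  if (spec$band_high >= fs / 2) {
    abort(sprintf("Band edge %g Hz at or above Nyquist (%g Hz).",
                  spec$band_high, fs / 2))
  }
}

# RBJ audio-cookbook biquad notch
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

design_bandpass <- function(low, high, fs, order) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

# Zero-phase IIR application with reflective padding of 3x the filter
# length at each end; forward pass, time-reverse, second pass, reverse.
filtfilt_refl <- function(b, a, x) {
  npad <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= npad) {
    abort(sprintf("Signal too short to filter: %d samples <= %d padding.",
                  n, npad))
  }
  # odd reflection about the end points suppresses edge steps
  left <- 2 * x[1] - x[seq(npad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xx <- c(left, x, right)
  y <- signal::filter(b, a, xx)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

apply_iir <- function(b, a, x, zero_phase = TRUE) {
  if (zero_phase) return(filtfilt_refl(b, a, x))
  as.numeric(signal::filter(b, a, x))
}

#' Remove power-line interference from one signal
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()].
#' @return Filtered vector of the same length.  Gain at the notch
#'   frequency is strongly attenuated; pass-band gain stays ~1.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  check_fs(fs, spec)
  d <- design_notch(spec$notch_freq, fs, spec$notch_q)
  apply_iir(d$b, d$a, x, spec$zero_phase)
}

#' Restrict one signal to the sleep-EEG band
#'
#' @inheritParams notch_filter
#' @return Filtered vector of the same length, DC removed.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  check_fs(fs, spec)
  d <- design_bandpass(spec$band_low, spec$band_high, fs, spec$butter_order)
  apply_iir(d$b, d$a, x, spec$zero_phase)
}

#' Preprocess a whole recording (notch, then band-pass)
#'
#' Channel-wise application of [notch_filter()] then [bandpass_filter()];
#' labels and sampling rate are unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec()) {
  check_fs(rec$fs, spec)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- bandpass_filter(notch_filter(out[i, ], rec$fs, spec),
                                rec$fs, spec)
  }
  eeg_recording(out, rec$channel_labels, rec$fs, rec$subject_id,
                rec$group_label)
}

#' Net magnitude response of the preprocessing chain
#'
#' Evaluates the designed transfer functions on the unit circle; with
#' zero-phase application the net gain is the squared single-pass
#' magnitude.  Used to verify attenuation/pass-band contracts against
#' measured signal RMS.
#'
#' @param freqs frequencies at which to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()].
#' @param stage `"notch"`, `"bandpass"`, or `"both"` (product).
#' @return A tibble with columns `freq` and `gain` (linear amplitude).
#' @export
filter_response <- function(freqs, fs, spec = filter_spec(),
                            stage = c("both", "notch", "bandpass")) {
  stage <- match.arg(stage)
  gain1 <- function(d, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- vapply(z, function(zz) {
      sum(d$b * zz^(seq_along(d$b) - 1)) / sum(d$a * zz^(seq_along(d$a) - 1))
    }, complex(1))
    Mod(h)
  }
  g <- rep(1, length(freqs))
  if (stage %in% c("both", "notch")) {
    g <- g * gain1(design_notch(spec$notch_freq, fs, spec$notch_q), freqs)
  }
  if (stage %in% c("both", "bandpass")) {
    g <- g * gain1(design_bandpass(spec$band_low, spec$band_high, fs,
                                   spec$butter_order), freqs)
  }
  if (spec$zero_phase) g <- g^2
  tibble(freq = freqs, gain = g)
}
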