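# Independent oracles used across the suite.

# Exhaustive Mann-Whitney two-sided p for tie-free samples: enumerate all
# C(n1+n2, n1) assignments of the pooled ranks to group 1 and count
# assignments with U at least as extreme (two-sided, doubled tail).
mww_enum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Fraction of a signal's periodogram power inside [f_low, f_high].
power_fraction <- function(x, fs, f_low, f_high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- pmin((0:(n - 1)) * fs / n, fs - (0:(n - 1)) * fs / n)
  sum(p[f >= f_low & f <= f_high]) / sum(p)
}

# Brute-force spectral ordering oracle: for each frequency position, a
# pure sine at the leaf's centre frequency must put maximal energy in the
# mapped natural-order leaf.
swept_sine_argmax <- function(level, fs = 200, n = 64 * 2^level) {
  t <- (0:(n - 1)) / fs
  width <- fs / 2 / 2^level
  vapply(0:(2^level - 1), function(p) {
    s <- sin(2 * pi * (p + 0.5) * width * t)
    tr <- wpd_decompose(s, wavelet_spec(level = level))
    which.max(vapply(tr$leaves, function(v) sum(v^2), numeric(1))) - 1L
  }, integer(1))
}

# Small 4-channel recording with known content for IO tests.
fixture_recording <- function(n = 600, fs = 200, seed = 42,
                              labels = c("F4-A1", "F3-A2", "O1-A2", "O2-A1")) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(length(labels) * n, sd = 40),
                         nrow = length(labels)),
                  labels, fs, subject_id = "fix", group_label = "UNKNOWN")
  })
}
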