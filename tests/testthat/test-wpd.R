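test_that("decomposition is perfectly invertible and energy preserving", {
  withr::with_seed(7, {
    for (n in c(32, 100, 777, 4096)) {  # includes non-multiples of 32
      x <- rnorm(n)
      tr <- wpd_decompose(x, wavelet_spec())
      expect_lt(max(abs(wpd_reconstruct(tr) - x)) / max(abs(x)), 1e-8)
      if (n %% 32 == 0) {
        # Parseval for the orthonormal periodized bank
        e <- sum(vapply(tr$leaves, function(v) sum(v^2), numeric(1)))
        expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
        expect_equal(sum(lengths(tr$leaves)), n)
      }
    }
  })
  expect_error(wpd_decompose(rnorm(16), wavelet_spec(level = 5)), "too short")
  expect_error(wavelet_spec(family = "sym5"), "Unknown wavelet")
})

test_that("a constant lands entirely in the all-low-pass leaf", {
  tr <- wpd_decompose(rep(3.7, 256), wavelet_spec())
  e <- vapply(tr$leaves, function(v) sum(v^2), numeric(1))
  expect_gt(e[1] / sum(e), 1 - 1e-10)
  expect_lt(max(e[-1]) / sum(e), 1e-10)
})

test_that("frequency ordering matches the swept-sine oracle at every level", {
  expect_identical(frequency_order(1), c(0L, 1L))
  expect_identical(frequency_order(2), c(0L, 1L, 3L, 2L))
  for (lev in 1:5) {
    expect_identical(swept_sine_argmax(lev), frequency_order(lev),
                     label = sprintf("level %d", lev))
  }
})

test_that("leaves map to bands by centre-frequency containment", {
  map <- band_leaf_map(200, 5)
  # leaf width 200 / 2 / 32 = 3.125 Hz
  expect_equal(map$delta, 0L)          # centre 1.5625 Hz
  expect_equal(map$theta, c(1L, 2L))   # 4.6875, 7.8125
  expect_equal(map$alpha, 3L)          # 10.9375
  expect_equal(map$beta, 4:9)          # 14.0625 .. 29.6875
  expect_equal(map$gamma, 10L)         # 32.8125

  overlapping <- tibble::tibble(band = c("a", "b"),
                                f_low = c(1, 3), f_high = c(5, 8))
  expect_error(band_leaf_map(200, 5, overlapping), "overlap")
  expect_error(band_leaf_map(40, 5), "below the highest band edge")
})

test_that("band extraction concentrates sine energy in the right band", {
  fs <- 200
  t <- (0:6399) / fs
  band_energy <- function(f_hz) {
    tr <- wpd_decompose(sin(2 * pi * f_hz * t), wavelet_spec())
    vapply(as.character(eeg_bands()$band), function(b) {
      sum(extract_band(tr, b, fs, reconstruct = FALSE)$abs_coeffs^2)
    }, numeric(1))
  }
  e2 <- band_energy(2)
  expect_gt(e2[["delta"]] / sum(e2), 0.9)  # delta dominates a 2 Hz sine
  e10 <- band_energy(10)
  expect_identical(names(which.max(e10)), "alpha")  # alpha is the argmax band

  tr0 <- wpd_decompose(rep(0, 640), wavelet_spec())
  expect_true(all(extract_band(tr0, "delta", fs)$abs_coeffs == 0))
})

test_that("a band owning no leaf raises an explicit empty-band error", {
  # at level 2 the leaves are 25 Hz wide; delta owns none of them
  tr <- wpd_decompose(rnorm(64), wavelet_spec(level = 2))
  expect_error(extract_band(tr, "delta", 200), "owns no leaf")
})

test_that("band signals plus residual reconstruct the input exactly", {
  withr::with_seed(11, x <- rnorm(3200))
  fs <- 200
  tr <- wpd_decompose(x, wavelet_spec())
  map <- band_leaf_map(fs, 5)
  ord <- frequency_order(5)
  parts <- lapply(names(map), function(b) {
    extract_band(tr, b, fs)$band_signal
  })
  assigned <- ord[unlist(map) + 1L]
  residual <- wpd_reconstruct(tr, keep = setdiff(0:31, assigned))
  total <- Reduce(`+`, parts) + residual
  expect_lt(max(abs(total - x)) / max(abs(x)), 1e-8)
})

test_that("leaf energy tidier is consistent with the frequency ordering", {
  fs <- 200
  t <- (0:6399) / fs
  # sine in frequency position 4 (beta's first leaf, centre 14.0625 Hz)
  tr <- wpd_decompose(sin(2 * pi * 14.0625 * t), wavelet_spec())
  td <- tidy(tr)
  expect_equal(nrow(td), 32)
  expect_equal(td$leaf_freq_pos[which.max(td$energy)], 4)
  expect_equal(sum(td$energy_frac), 1)
})
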