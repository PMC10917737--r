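test_that("band-limited noise is confined, unit variance, deterministic", {
  y <- band_limited_noise(0.5, 4, 200, 60000, seed = 101)
  expect_gt(power_fraction(y, 200, 0.5, 4), 0.95)
  expect_lt(abs(var(y) - 1), 0.01)
  expect_identical(y, band_limited_noise(0.5, 4, 200, 60000, seed = 101))
  expect_false(identical(y, band_limited_noise(0.5, 4, 200, 60000, seed = 102)))
  expect_error(band_limited_noise(30, 120, 200, 1000, 1), "outside")
})

test_that("Cholesky mixing reaches the target correlation", {
  id <- diag(4)
  m <- coupled_channels(id, 0.5, 4, 200, 60000, seed = 31)
  r <- cor(t(m))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  tgt <- matrix(0.9, 4, 4); diag(tgt) <- 1
  m <- coupled_channels(tgt, 0.5, 4, 200, 60000, seed = 32)
  r <- cor(t(m))
  expect_lt(max(abs(r[upper.tri(r)] - 0.9)), 0.03)

  bad <- matrix(0.9, 4, 4); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.9
  err <- expect_error(coupled_channels(bad, 0.5, 4, 200, 1000, 1),
                      "positive semidefinite")
  expect_match(conditionMessage(err), "eigenvalue")
})

test_that("subject generation is reproducible and respects preset ranges", {
  sp <- cohort_spec(n_osa = 2, n_healthy = 2, duration_s = 30, seed = 77)
  s1 <- generate_subject(sp, "OSA", 1)
  s2 <- generate_subject(sp, "OSA", 1)
  expect_identical(s1$recording$data, s2$recording$data)
  s3 <- generate_subject(sp, "OSA", 2)
  expect_false(identical(s1$recording$data, s3$recording$data))
  expect_gte(s1$coupling[["delta"]], 0.75)
  expect_lte(s1$coupling[["delta"]], 0.90)
  h <- generate_subject(sp, "HEALTHY", 1)
  expect_gte(h$coupling[["delta"]], 0.45)
  expect_lte(h$coupling[["delta"]], 0.65)
  expect_identical(dim(s1$recording$data), c(4L, 6000L))
})

test_that("cohort generation writes a faithful, reproducible manifest", {
  sp <- cohort_spec(n_osa = 2, n_healthy = 2, duration_s = 10, seed = 13)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(sp, dir = dir)
  expect_equal(nrow(cohort$manifest), 4)
  expect_true(all(cohort$manifest$coupling_delta[cohort$manifest$group == "OSA"]
                  >= 0.75))
  expect_true(all(cohort$manifest$coupling_delta[cohort$manifest$group == "HEALTHY"]
                  <= 0.65))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$root_seed, 13)
  expect_equal(man$subjects$seed, cohort$manifest$seed)
  # recordings round-trip through the columnar format
  r <- read_columnar(file.path(dir, "osa_001.tsv"))
  expect_identical(r$data, cohort$subjects[[1]]$recording$data)
  # collisions and empty groups are rejected
  expect_error(generate_cohort(sp, dir = dir), "collision")
  expect_error(generate_cohort(cohort_spec(n_osa = 0, n_healthy = 2)),
               "at least one subject")
})

test_that("pipeline recovers the prescribed band-signal coupling", {
  # delta-only cohort, no pink floor: extraction is linear and identical
  # across channels, so band-signal correlation estimates the target
  for (rho in c(0.2, 0.8)) {
    sp <- cohort_spec(
      n_osa = 1, n_healthy = 1, duration_s = 300,
      coupling = list(delta = list(osa = rho, healthy = rho)),
      band_powers = c(delta = 1), pink_floor = 0, seed = 55
    )
    rec <- preprocess_recording(generate_subject(sp, "OSA", 1)$recording)
    trees <- apply(rec$data, 1, wpd_decompose, spec = wavelet_spec(),
                   simplify = FALSE)
    sig <- vapply(trees, function(tr) {
      extract_band(tr, "delta", rec$fs)$band_signal
    }, numeric(ncol(rec$data)))
    r <- cor(sig)
    est <- mean(r[upper.tri(r)])
    expect_lt(abs(est - rho), 0.05, label = sprintf("rho = %g", rho))
  }
})
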