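test_that("exact Mann-Whitney p matches exhaustive enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic_U, 0)
  expect_equal(r$p_two_sided, 0.1)  # 2/20 assignments
  expect_identical(r$method, "exact")

  withr::with_seed(21, {
    for (n1 in 2:5) {
      for (n2 in 2:5) {
        a <- runif(n1)
        b <- runif(n2) + runif(1, -0.5, 0.5)
        got <- mann_whitney(a, b)
        expect_identical(got$method, "exact")
        expect_equal(got$p_two_sided, mww_enum_p(a, b),
                     tolerance = 1e-12,
                     label = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  })
})

test_that("U statistics satisfy U1 + U2 = n1 n2, with and without ties", {
  withr::with_seed(22, {
    for (i in 1:30) {
      n1 <- sample(1:30, 1)
      n2 <- sample(1:30, 1)
      a <- sample(1:10, n1, replace = TRUE)  # heavy ties
      b <- sample(1:10, n2, replace = TRUE)
      u1 <- mann_whitney(a, b)$statistic_U
      u2 <- mann_whitney(b, a)$statistic_U
      expect_equal(u1 + u2, n1 * n2)
    }
  })
})

test_that("degenerate and tied configurations give p = 1", {
  r <- mann_whitney(c(1, 2), c(1, 2))  # complete ties
  expect_equal(r$statistic_U, 2)       # n1 n2 / 2 from midranks
  expect_equal(r$p_two_sided, 1)

  r1 <- mann_whitney(1, 2)  # single-subject groups: no power
  expect_identical(r1$method, "exact")
  expect_equal(r1$p_two_sided, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("normal-approximation path agrees with wilcox.test", {
  withr::with_seed(23, {
    a <- rnorm(60)
    b <- rnorm(55, 0.3)
  })
  got <- mann_whitney(a, b)
  expect_identical(got$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(got$statistic_U, unname(ref$statistic))
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
})

test_that("per-band comparison flags only truly different bands", {
  feats <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:12),
    band = c("delta", "alpha")
  )
  feats$group <- rep(c("OSA", "HEALTHY"), each = 12)
  withr::with_seed(24, {
    feats$value <- ifelse(feats$band == "delta" & feats$group == "OSA",
                          rnorm(nrow(feats), 2, 0.3),
                          rnorm(nrow(feats), 0, 0.3))
  })
  res <- compare_bands(feats)
  expect_s3_class(res, "osa_band_tests")
  expect_true(res$significant[res$band == "delta"])
  expect_false(res$significant[res$band == "alpha"])

  # identical groups: complete cross-group ties, p = 1 everywhere
  feats$value <- (match(feats$subject_id, sprintf("s%02d", 1:12)) - 1) %% 6
  res <- compare_bands(feats)
  expect_true(all(res$p_value == 1))

  feats$group <- "OSA"
  expect_error(compare_bands(feats), "two groups")
})

test_that("degree t-maps follow the Welch formula", {
  withr::with_seed(25, {
    d1 <- matrix(rnorm(40, 5), 10, 4, dimnames = list(NULL, paste0("n", 1:4)))
    d2 <- matrix(rnorm(40, 5), 10, 4, dimnames = list(NULL, paste0("n", 1:4)))
  })
  tm <- degree_t_map(d1, d2)
  for (j in 1:4) {
    ref <- stats::t.test(d1[, j], d2[, j])
    expect_equal(tm$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tm$df[j], unname(ref$parameter), tolerance = 1e-12)
  }

  # separation 3 vs 1 with sd 0.1 jitter: |t| > 10
  withr::with_seed(26, {
    g1 <- matrix(3 + rnorm(40, sd = 0.1), 10, 4)
    g2 <- matrix(1 + rnorm(40, sd = 0.1), 10, 4)
  })
  expect_true(all(abs(degree_t_map(g1, g2)$t) > 10))

  # identical means/variances -> t ~ 0; constant equal degrees -> missing
  tm0 <- degree_t_map(d1, d1)
  expect_true(all(abs(tm0$t) < 1e-12))
  cst <- matrix(2, 5, 4)
  expect_true(all(is.na(degree_t_map(cst, cst)$t)))
  expect_error(degree_t_map(d1[1, , drop = FALSE], d2), ">= 2 subjects")
})

test_that("t-map vs network-map correlation reuses the pearson contract", {
  tm <- degree_t_map(matrix(rnorm(40), 10, 4), matrix(rnorm(40), 10, 4))
  expect_equal(correlate_t_with_network(tm, stats::setNames(tm$t, tm$node)), 1)
  expect_equal(correlate_t_with_network(tm, stats::setNames(-tm$t, tm$node)), -1)

  tm$t <- c(1, 2, 3, 4)
  ref <- data.frame(node = tm$node, value = c(1, 3, 2, 4))
  expect_equal(correlate_t_with_network(tm, ref), 0.8)

  tm$t <- c(1, NA, NA, 4)
  expect_error(correlate_t_with_network(tm, ref), ">= 3 nodes")
})
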