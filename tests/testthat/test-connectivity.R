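make_feat <- function(m) {
  rownames(m) <- c("F4-A1", "F3-A2", "O1-A2", "O2-A1")[seq_len(nrow(m))]
  m
}

test_that("pearson matches hand computations and the textbook formula", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)  # cov 4, sd^2 5
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:4, 1:5), "equal length")
  expect_error(pearson(1:2, 2:1), "at least 3")
  withr::with_seed(3, {
    for (i in 1:100) {
      x <- rnorm(50)
      y <- rnorm(50)
      expect_lt(abs(pearson(x, y) - cor(x, y)), 1e-12)
    }
  })
})

test_that("band connectivity averages per-epoch correlations correctly", {
  # 4 identical channels -> all entries 1
  one <- make_feat(matrix(rep(rnorm(100), 4), 4, byrow = TRUE))
  m <- band_connectivity(list(one), band = "delta")
  expect_true(all(abs(m$r - 1) < 1e-12))
  expect_identical(diag(m$r), stats::setNames(rep(1, 4), rownames(one)))

  # independent white noise: off-diagonals within the sampling bound
  withr::with_seed(5, {
    eps <- lapply(1:10, function(i) make_feat(matrix(rnorm(4 * 3000), 4)))
  })
  m <- band_connectivity(eps, band = "delta")
  expect_lt(max(abs(m$r[upper.tri(m$r)])), 0.08)  # ~3 / sqrt(n * epochs)

  # common source + equal-variance noise -> r ~ 0.5
  withr::with_seed(6, {
    s <- rnorm(3000)
    eps <- lapply(1:4, function(i) {
      make_feat(rbind(s + rnorm(3000), s + rnorm(3000),
                      s + rnorm(3000), s + rnorm(3000)))
    })
  })
  m <- band_connectivity(eps, band = "delta")
  expect_lt(max(abs(m$r[upper.tri(m$r)] - 0.5)), 0.05)
})

test_that("degenerate epochs are excluded with a warning, all-degenerate errors", {
  good <- make_feat(matrix(rnorm(4 * 100), 4))
  bad <- good
  bad[2, ] <- 7  # constant channel
  expect_warning(m <- band_connectivity(list(good, bad)), "Excluding 1 epoch")
  m2 <- band_connectivity(list(good))
  expect_equal(m$r, m2$r)
  expect_error(suppressWarnings(band_connectivity(list(bad))), "All epochs")
})

test_that("connectivity is invariant to channel order and feature scale", {
  withr::with_seed(8, feat <- make_feat(matrix(rnorm(4 * 500), 4)))
  m <- band_connectivity(list(feat))
  perm <- c(3, 1, 4, 2)
  mp <- band_connectivity(list(feat[perm, ]))
  expect_equal(mp$r, m$r[perm, perm])
  scaled <- feat
  scaled[1, ] <- 13.7 * scaled[1, ]
  expect_equal(band_connectivity(list(scaled))$r, m$r)
})

test_that("positive-edge rule, degrees, and the handshake lemma", {
  base <- make_feat(matrix(rnorm(4 * 100), 4))
  m <- band_connectivity(list(base), band = "delta")

  m$r[,] <- 0.5; diag(m$r) <- 1
  g <- positive_edges(m)
  expect_equal(nrow(g$edges), 6)
  expect_true(all(g$nodes$degree == 3))

  m$r[,] <- -0.2; diag(m$r) <- 1
  g <- positive_edges(m)
  expect_equal(nrow(g$edges), 0)
  expect_true(all(g$nodes$degree == 0))

  m$r[,] <- -0.3; diag(m$r) <- 1
  m$r[1, 2] <- m$r[2, 1] <- 0.9
  g <- positive_edges(m)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$nodes$degree, c(1, 1, 0, 0))

  # handshake lemma over random matrices and thresholds
  withr::with_seed(9, {
    for (i in 1:20) {
      mm <- band_connectivity(list(make_feat(matrix(rnorm(4 * 50), 4))))
      gg <- positive_edges(mm, threshold = runif(1, 0, 0.5))
      expect_equal(sum(gg$nodes$degree), 2 * nrow(gg$edges))
    }
  })

  # missing coordinates are an error
  expect_error(
    positive_edges(m, coords = tibble::tibble(label = "F4-A1",
                                              x = 0, y = 0, z = 0)),
    "Missing coordinates"
  )
})

test_that("group min/max summarize positive off-diagonals across subjects", {
  mk <- function(vals) {
    m <- diag(4)
    m[upper.tri(m)] <- vals
    m <- m + t(m) - diag(diag(m))
    x <- band_connectivity(list(make_feat(matrix(rnorm(400), 4))), band = "delta")
    x$r <- m
    x
  }
  s <- group_min_max(list(mk(c(0.2, 0.5, -0.1, 0.7, 0.3, 0.4))), group = "OSA")
  expect_equal(c(s$min_pos_r, s$max_pos_r), c(0.2, 0.7))
  expect_false(s$empty)

  s2 <- group_min_max(list(mk(c(0.3, rep(-1, 5))), mk(c(0.6, rep(-1, 5)))))
  expect_equal(c(s2$min_pos_r, s2$max_pos_r), c(0.3, 0.6))

  s3 <- group_min_max(list(mk(rep(-0.5, 6))))
  expect_true(s3$empty)
  expect_true(is.na(s3$min_pos_r))
})

test_that("BrainNet node/edge files round-trip losslessly", {
  withr::with_seed(10, feat <- make_feat(matrix(rnorm(4 * 200), 4)))
  m <- band_connectivity(list(feat), band = "beta")
  g <- positive_edges(m)
  np <- withr::local_tempfile(fileext = ".node")
  ep <- withr::local_tempfile(fileext = ".edge")
  export_brainnet(g, np, ep)
  g2 <- read_brainnet(np, ep, band = "beta")
  expect_equal(as.data.frame(g2$nodes), as.data.frame(g$nodes))
  expect_equal(as.data.frame(dplyr::arrange(g2$edges, from, to)),
               as.data.frame(dplyr::arrange(g$edges, from, to)))

  # K4 with unit weights: 4x4 edge matrix, zero diagonal, ones elsewhere
  m$r[,] <- 1
  gk <- positive_edges(m)
  export_brainnet(gk, np, ep)
  w <- as.matrix(read.table(ep))
  expect_equal(unname(w), matrix(1, 4, 4) - diag(4))
  nd <- read.table(np)
  expect_equal(nd$V5, rep(3, 4))  # size column carries degree

  # empty graph: all-zero edge matrix, zero sizes
  m$r[,] <- -1; diag(m$r) <- 1
  export_brainnet(positive_edges(m), np, ep)
  expect_true(all(as.matrix(read.table(ep)) == 0))
  expect_true(all(read.table(np)$V5 == 0))
})
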