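# Exact null distribution of the Mann-Whitney U statistic for tie-free
# samples: counts N(u; m, n) of the C(m+n, m) rank assignments with U = u,
# via the standard lattice recursion N(u; m, n) = N(u-n; m-1, n) + N(u; m, n-1).
mww_exact_counts <- function(n1, n2) {
  umax <- n1 * n2
  cnt <- array(0, dim = c(n1 + 1L, n2 + 1L, umax + 1L))
  cnt[1, , 1] <- 1
  cnt[, 1, 1] <- 1
  for (m in seq_len(n1)) {
    for (n in seq_len(n2)) {
      for (u in 0:(m * n)) {
        lower <- if (u - n >= 0) cnt[m, n + 1L, u - n + 1L] else 0
        cnt[m + 1L, n + 1L, u + 1L] <- lower + cnt[m + 1L, n, u + 1L]
      }
    }
  }
  cnt[n1 + 1L, n2 + 1L, ]
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Rank-based test of stochastic ordering between two independent
#' samples, built from the U statistic on midranks.  For small tie-free
#' samples (`n1 * n2 <= 400`) the two-sided p-value is exact, from the
#' full null distribution of U; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param a,b numeric vectors (the two groups), each non-empty.
#' @return An `osa_mww` object: `statistic_U` (U of group `a`),
#'   `statistic_z`, `p_two_sided`, `n1`, `n2`, `method`
#'   (`"exact"`/`"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1 exactly
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("Both groups must be non-empty.")
  n1 <- length(a); n2 <- length(b); nn <- n1 + n2
  r <- rank(c(a, b))  # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n1 * n2 <= 400) {
    cnt <- mww_exact_counts(n1, n2)
    total <- sum(cnt)
    k <- round(u1)  # integer for tie-free data
    p_lo <- sum(cnt[seq_len(k + 1L)]) / total
    p_hi <- sum(cnt[(k + 1L):length(cnt)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    # informational standardized U alongside the exact p
    z <- (u1 - n1 * n2 / 2) / sqrt(n1 * n2 * (nn + 1) / 12)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      z <- 0; p <- 1
    } else {
      d <- u1 - mu
      z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(
    list(statistic_U = u1, statistic_z = z, p_two_sided = p,
         n1 = n1, n2 = n2, method = method),
    class = "osa_mww"
  )
}

#' @export
print.osa_mww <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon (%s): U = %g, z = %.3f, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic_U, x$statistic_z, x$p_two_sided,
              x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.osa_mww <- function(x, ...) {
  tibble(statistic_U = x$statistic_U, statistic_z = x$statistic_z,
         p_value = x$p_two_sided, n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Per-band nonparametric group comparison
#'
#' Runs one Mann-Whitney-Wilcoxon test per frequency band on a chosen
#' per-subject scalar summary, flagging bands significant at `alpha`.
#' No multiple-testing correction is applied by default (raw p-values);
#' set `p_adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param features tibble with columns `subject_id`, `group`, `band`,
#'   and `value` (the per-subject per-band summary, e.g. mean absolute
#'   wavelet coefficient, or mean positive correlation).
#' @param alpha significance level (default 0.05).
#' @param p_adjust apply Benjamini-Hochberg across bands? Default `FALSE`.
#' @return An `osa_band_tests` tibble: one row per band with `statistic_U`,
#'   `statistic_z`, `p_value`, group sizes, `method`, `significant`.
#' @export
compare_bands <- function(features, alpha = 0.05, p_adjust = FALSE) {
  stopifnot(all(c("subject_id", "group", "band", "value") %in% names(features)))
  groups <- sort(unique(as.character(features$group)))
  if (length(groups) != 2) {
    abort(sprintf("Exactly two groups required, found: %s",
                  paste(groups, collapse = ", ")))
  }
  out <- features |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$group == groups[1]]
      b <- d$value[d$group == groups[2]]
      if (length(a) == 0 || length(b) == 0) {
        abort(sprintf("Band %s: a group is empty.", key$band))
      }
      tidy(mann_whitney(a, b))
    }) |>
    dplyr::ungroup()
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  class(out) <- c("osa_band_tests", class(out))
  out
}

#' Welch t statistics of node degree between groups
#'
#' One two-sample Welch t per node (brain region), comparing node degrees
#' between groups.  Nodes where the standard error is zero (both groups
#' degenerate) get a missing t.
#'
#' @param degrees_group1,degrees_group2 subjects x nodes numeric matrices
#'   (columns named by node label); at least 2 subjects per group.
#' @return An `osa_tmap` tibble: `node`, `t`, `df`, `mean1`, `mean2`.
#' @export
degree_t_map <- function(degrees_group1, degrees_group2) {
  d1 <- as.matrix(degrees_group1); d2 <- as.matrix(degrees_group2)
  if (nrow(d1) < 2 || nrow(d2) < 2) abort("Need >= 2 subjects per group.")
  if (ncol(d1) != ncol(d2)) abort("Groups disagree on the node set.")
  nodes <- colnames(d1) %||% paste0("node", seq_len(ncol(d1)))
  n1 <- nrow(d1); n2 <- nrow(d2)
  m1 <- colMeans(d1); m2 <- colMeans(d2)
  v1 <- apply(d1, 2, var); v2 <- apply(d2, 2, var)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  out <- tibble(node = nodes, t = unname(t), df = unname(df),
                mean1 = unname(m1), mean2 = unname(m2))
  class(out) <- c("osa_tmap", class(out))
  out
}

#' Correlate a node t-map with a reference network map
#'
#' Pearson correlation, over nodes with a defined t, between the group
#' t statistics and a per-node reference map (e.g. a group-mean degree
#' map), quantifying how well the group contrast follows the network.
#'
#' @param t_map an `osa_tmap` from [degree_t_map()].
#' @param network_map named numeric vector (names = node labels) or a
#'   tibble/data.frame with columns `node` and `value`.
#' @return Pearson r over the common nodes (>= 3 required).
#' @export
correlate_t_with_network <- function(t_map, network_map) {
  if (is.data.frame(network_map)) {
    ref <- stats::setNames(network_map$value, network_map$node)
  } else {
    ref <- network_map
    if (is.null(names(ref))) names(ref) <- t_map$node
  }
  keep <- !is.na(t_map$t) & t_map$node %in% names(ref)
  if (sum(keep) < 3) abort("Need >= 3 nodes with a defined t statistic.")
  pearson(t_map$t[keep], as.numeric(ref[t_map$node[keep]]))
}
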