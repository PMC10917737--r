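#' Pearson product-moment correlation
#'
#' Small, explicit implementation used for all connectivity and map
#' correlations so that degenerate inputs fail loudly: constant vectors
#' raise an error instead of silently returning 0 or NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) {
    abort("Correlation undefined: at least one input is constant.")
  }
  max(-1, min(1, sum(xc * yc) / (sx * sy)))
}

new_connectivity <- function(r, band, channel_labels, n_obs, n_epochs) {
  dimnames(r) <- list(channel_labels, channel_labels)
  structure(
    list(band = band, channel_labels = channel_labels, r = r,
         n_obs = n_obs, n_epochs = n_epochs),
    class = "osa_connectivity"
  )
}

#' @export
print.osa_connectivity <- function(x, ...) {
  cat(sprintf("<osa_connectivity> band %s (%d epoch(s), %d obs/correlation)\n",
              x$band, x$n_epochs, x$n_obs))
  print(round(x$r, 4))
  invisible(x)
}

#' Channel-by-channel correlation of absolute wavelet coefficients
#'
#' Builds one band's connectivity matrix: for every epoch, the Pearson
#' correlation between each pair of channels' absolute-coefficient
#' vectors; entries are then averaged across epochs (optionally through
#' the Fisher z transform).  Epochs where any channel's feature vector is
#' constant are excluded with a warning.
#'
#' @param epoch_features list with one element per epoch, each a
#'   channels x coefficients numeric matrix (rows named by channel).
#' @param band band name stored on the result.
#' @param fisher_z average r across epochs on the z scale (`atanh`)
#'   instead of the plain mean?  Default `FALSE`.
#' @return An `osa_connectivity`: symmetric matrix, unit diagonal.
#' @export
band_connectivity <- function(epoch_features, band = "band",
                              fisher_z = FALSE) {
  stopifnot(is.list(epoch_features), length(epoch_features) >= 1)
  labels <- rownames(epoch_features[[1]]) %||%
    paste0("ch", seq_len(nrow(epoch_features[[1]])))
  nch <- nrow(epoch_features[[1]])
  ok <- vapply(epoch_features, function(m) {
    all(apply(m, 1, function(v) sd(v) > 0))
  }, logical(1))
  if (!all(ok)) {
    warn(sprintf("Excluding %d epoch(s) with a constant channel feature vector.",
                 sum(!ok)))
  }
  epoch_features <- epoch_features[ok]
  if (length(epoch_features) == 0) {
    abort("All epochs excluded: every epoch had a constant channel.")
  }
  acc <- matrix(0, nch, nch)
  for (m in epoch_features) {
    r <- diag(nch)
    for (i in seq_len(nch - 1)) {
      for (j in (i + 1):nch) {
        r[i, j] <- r[j, i] <- pearson(m[i, ], m[j, ])
      }
    }
    acc <- acc + if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
  }
  r_bar <- acc / length(epoch_features)
  if (fisher_z) r_bar <- tanh(r_bar)
  diag(r_bar) <- 1
  new_connectivity(r_bar, band, labels, ncol(epoch_features[[1]]),
                   length(epoch_features))
}

#' Connectivity matrix as an edge tibble
#'
#' @param x an `osa_connectivity`.
#' @param ... unused.
#' @return Tibble with one row per unordered channel pair: `band`,
#'   `from`, `to`, `r`.
#' @export
tidy.osa_connectivity <- function(x, ...) {
  nch <- length(x$channel_labels)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    band = x$band,
    from = x$channel_labels[pairs[, 1]],
    to = x$channel_labels[pairs[, 2]],
    r = x$r[pairs]
  )
}

#' Default scalp coordinates for the four ISRUC derivations
#'
#' Approximate MNI positions (mm) of the 10-20 electrode sites F3, F4,
#' O1, O2; rows are keyed by the EEG channel label whose active electrode
#' sits there.  Purely presentational (BrainNet export); override with
#' your own table for other montages.
#'
#' @return Tibble with columns `label`, `x`, `y`, `z`.
#' @export
default_node_coords <- function() {
  tibble(
    label = c("F3-A2", "F4-A1", "O1-A2", "O2-A1"),
    x = c(-39, 39, -26, 26),
    y = c(47, 47, -94, -94),
    z = c(33, 33, 8, 8)
  )
}

#' Positive-correlation graph of a connectivity matrix
#'
#' Retains the undirected edge (i, j), i < j, iff `r_ij > threshold`
#' (default 0: strictly positive correlations).  Self-loops are never
#' emitted; node degree is the number of retained incident edges.
#'
#' @param m an `osa_connectivity`.
#' @param threshold minimum correlation for an edge (default 0).
#' @param coords node coordinate table with columns `label, x, y, z`;
#'   labels are matched tolerantly.  Default [default_node_coords()].
#' @return An `osa_graph`: `nodes` tibble (`label, x, y, z, degree`),
#'   `edges` tibble (`from, to, weight`), plus `band` and `threshold`.
#' @export
positive_edges <- function(m, threshold = 0, coords = default_node_coords()) {
  stopifnot(inherits(m, "osa_connectivity"), threshold >= 0)
  labels <- m$channel_labels
  idx <- match(normalize_label(labels), normalize_label(coords$label))
  if (anyNA(idx)) {
    abort(sprintf("Missing coordinates for node(s): %s",
                  paste(labels[is.na(idx)], collapse = ", ")))
  }
  pairs <- which(upper.tri(m$r), arr.ind = TRUE)
  kept <- m$r[pairs] > threshold
  edges <- tibble(
    from = labels[pairs[kept, 1]],
    to = labels[pairs[kept, 2]],
    weight = m$r[pairs][kept]
  )
  degree <- vapply(labels, function(l) sum(edges$from == l | edges$to == l),
                   numeric(1))
  nodes <- tibble(
    label = labels,
    x = coords$x[idx], y = coords$y[idx], z = coords$z[idx],
    degree = as.numeric(degree)
  )
  structure(list(nodes = nodes, edges = edges, band = m$band,
                 threshold = threshold),
            class = "osa_graph")
}

#' @export
print.osa_graph <- function(x, ...) {
  cat(sprintf("<osa_graph> band %s: %d nodes, %d edges (r > %g)\n",
              x$band, nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' @export
tidy.osa_graph <- function(x, ...) x$edges

#' @export
glance.osa_graph <- function(x, ...) {
  tibble(band = x$band, n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold, total_degree = sum(x$nodes$degree))
}

#' Group-level extremes of positive correlation
#'
#' Scans all subjects' matrices for one band and group and reports the
#' minimum and maximum positive off-diagonal correlation across the whole
#' group (the summary the per-band group contrast is described by).
#'
#' @param matrices list of `osa_connectivity` for one band and group.
#' @param band,group labels stored on the summary row (default taken from
#'   the first matrix / `"group"`).
#' @return One-row tibble: `band`, `group`, `min_pos_r`, `max_pos_r`,
#'   `n_subjects`, `empty` (`TRUE` when no positive off-diagonal exists;
#'   the extremes are then `NA`).
#' @export
group_min_max <- function(matrices, band = NULL, group = "group") {
  stopifnot(length(matrices) >= 1)
  pos <- unlist(lapply(matrices, function(m) {
    v <- m$r[upper.tri(m$r)]
    v[v > 0]
  }))
  tibble(
    band = band %||% matrices[[1]]$band,
    group = group,
    min_pos_r = if (length(pos)) min(pos) else NA_real_,
    max_pos_r = if (length(pos)) max(pos) else NA_real_,
    n_subjects = length(matrices),
    empty = length(pos) == 0
  )
}
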