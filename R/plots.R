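#' Heatmap of a connectivity matrix
#'
#' @param object an `osa_connectivity`.
#' @param ... unused.
#' @return A ggplot: channel-by-channel tile map of Pearson r.
#' @export
autoplot.osa_connectivity <- function(object, ...) {
  df <- expand.grid(from = object$channel_labels,
                    to = object$channel_labels,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$r <- as.vector(object$r)
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(title = sprintf("%s band connectivity", object$band),
                  x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Per-band group-test p-values
#'
#' @param object an `osa_band_tests` tibble from [compare_bands()].
#' @param ... unused.
#' @return A ggplot: -log10 p per band with the significance line.
#' @export
autoplot.osa_band_tests <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$band, -log10(.data$p_value),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#B2182B")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Per-band group contrast") +
    ggplot2::theme_minimal()
}

#' Group-mean connectivity overview of a report
#'
#' @param object an `osa_report`.
#' @param ... unused.
#' @return A ggplot: tile maps of group-mean r, bands x groups facets.
#' @export
autoplot.osa_report <- function(object, ...) {
  df <- purrr::map_dfr(names(object$group_mean_connectivity), function(g) {
    purrr::map_dfr(names(object$group_mean_connectivity[[g]]), function(b) {
      m <- object$group_mean_connectivity[[g]][[b]]
      d <- expand.grid(from = m$channel_labels, to = m$channel_labels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      d$r <- as.vector(m$r)
      d$group <- g
      d$band <- b
      d
    })
  })
  df$band <- factor(df$band, levels = unique(df$band))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(group ~ band) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Group-mean band connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
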