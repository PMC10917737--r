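#' Export a graph in BrainNet Viewer node/edge formats
#'
#' Writes the two whitespace-separated text files BrainNet Viewer's
#' surface renderer consumes: the `.node` file has one row per node with
#' columns `x y z color size label` (size carries the node degree), and
#' the `.edge` file holds the full symmetric weight matrix with zeros
#' where no edge was retained and on the diagonal.
#'
#' @param g an `osa_graph` from [positive_edges()].
#' @param node_path,edge_path output file paths.
#' @param color node color column value (single number or one per node).
#' @return Invisibly, a list with the two paths.
#' @seealso [read_brainnet()] for the round-trip reader.
#' @export
export_brainnet <- function(g, node_path, edge_path, color = 1) {
  stopifnot(inherits(g, "osa_graph"))
  n <- nrow(g$nodes)
  color <- rep_len(color, n)
  # labels must be single tokens in the whitespace-separated format
  lab <- gsub("[[:space:]]+", "_", g$nodes$label)
  node_rows <- sprintf("%g\t%g\t%g\t%g\t%g\t%s",
                       g$nodes$x, g$nodes$y, g$nodes$z, color,
                       g$nodes$degree, lab)
  writeLines(node_rows, node_path)
  w <- matrix(0, n, n)
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, g$nodes$label)
    j <- match(g$edges$to, g$nodes$label)
    w[cbind(i, j)] <- g$edges$weight
    w[cbind(j, i)] <- g$edges$weight
  }
  writeLines(apply(w, 1, function(r) {
    paste(format(r, digits = 17, trim = TRUE), collapse = "\t")
  }), edge_path)
  invisible(list(node = node_path, edge = edge_path))
}

#' Read a BrainNet Viewer node/edge file pair back into a graph
#'
#' @param node_path,edge_path paths written by [export_brainnet()] (or by
#'   any tool emitting the standard column layout).
#' @param band,threshold metadata restored on the graph.
#' @return An `osa_graph`.
#' @export
read_brainnet <- function(node_path, edge_path, band = "band",
                          threshold = 0) {
  nd <- read.table(node_path, header = FALSE,
                   col.names = c("x", "y", "z", "color", "size", "label"),
                   colClasses = c(rep("numeric", 5), "character"))
  w <- as.matrix(read.table(edge_path, header = FALSE))
  dimnames(w) <- NULL
  if (nrow(w) != nrow(nd) || ncol(w) != nrow(nd)) {
    abort("Edge matrix dimensions do not match the node table.")
  }
  pairs <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  edges <- tibble(
    from = nd$label[pairs[, 1]],
    to = nd$label[pairs[, 2]],
    weight = w[pairs]
  )
  nodes <- tibble(label = nd$label, x = nd$x, y = nd$y, z = nd$z,
                  degree = nd$size)
  structure(list(nodes = nodes, edges = edges, band = band,
                 threshold = threshold),
            class = "osa_graph")
}
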