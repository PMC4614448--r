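#' Horizontal visibility graph of an ordered series
#'
#' Two time points `i < j` of a series `x` are linked in the horizontal
#' visibility graph (HVG) when every intermediate datum lies strictly below
#' the smaller of the two endpoints: `x[k] < min(x[i], x[j])` for all
#' `i < k < j`. Consecutive points are always linked, the graph is connected,
#' and no two edges cross when nodes are drawn on the time line
#' (outerplanarity). Ties block visibility: an intermediate value equal to
#' the smaller endpoint breaks the strict inequality. This convention matters
#' for quantized data (e.g. prices); it is irrelevant for continuous-state
#' chaotic series where exact ties have measure zero.
#'
#' The construction is a single left-to-right pass over the series using a
#' monotone stack, with expected linear cost on noisy data (each point is
#' pushed and popped once; the edge count of an HVG is at most `2N - 3`).
#'
#' @param x numeric vector, the ordered series (length at least 2, all
#'   values finite).
#' @param label optional channel label stored with the graph.
#' @return An object of class `visibility_graph`: a list with `n_nodes`,
#'   an `edges` matrix (two columns, 1-based node indices, `i < j`, sorted
#'   lexicographically) and `label`.
#' @examples
#' g <- build_hvg(c(3, 1, 2))
#' g$edges           # the triangle on 3 nodes
#' degree_sequence(g)
#' @seealso [build_nvg()] for the natural (convexity) visibility variant,
#'   [build_multiplex()] for the layer-per-channel multiplex.
#' @export
build_hvg <- function(x, label = NULL) {
  x <- check_series(x)
  edges <- hvg_edges_cpp(x)
  new_visibility_graph(length(x), sort_edges(edges), label)
}

#' Natural visibility graph of an ordered series
#'
#' Links `i < j` when every intermediate point lies strictly below the
#' straight line joining `(i, x[i])` and `(j, x[j])` (a convexity criterion).
#' The horizontal visibility graph of the same series is always a subgraph.
#' Collinear intermediate points block visibility (strict inequality).
#'
#' @inheritParams build_hvg
#' @return A `visibility_graph` object.
#' @export
build_nvg <- function(x, label = NULL) {
  x <- check_series(x)
  n <- length(x)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1L)) {
    # j is visible from i iff its slope strictly beats every earlier slope
    # from i; a collinear intermediate (equal slope) blocks
    max_slope <- -Inf
    for (j in (i + 1L):n) {
      slope <- (x[j] - x[i]) / (j - i)
      if (slope > max_slope) {
        ei <- c(ei, i); ej <- c(ej, j)
      }
      max_slope <- max(max_slope, slope)
    }
  }
  edges <- cbind(ei, ej, deparse.level = 0)
  storage.mode(edges) <- "integer"
  new_visibility_graph(n, sort_edges(edges), label)
}

#' Degree sequence of a visibility graph
#'
#' @param graph a `visibility_graph`.
#' @return Integer vector of length `n_nodes`; entry `i` counts the edges
#'   incident on node `i`.
#' @export
degree_sequence <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  tabulate(graph$edges, nbins = graph$n_nodes)
}

#' Empirical degree distribution of a visibility graph
#'
#' @param graph a `visibility_graph`.
#' @return Named numeric vector: `P(k)` indexed by the observed degrees `k`,
#'   summing to one.
#' @export
degree_distribution <- function(graph) {
  k <- degree_sequence(graph)
  tab <- table(k)
  setNames(as.numeric(tab) / graph$n_nodes, names(tab))
}

# fast path used by the multiplex metrics: degrees without edge storage
hvg_degree_sequence <- function(x) {
  hvg_degrees_cpp(check_series(x))
}

check_series <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) {
    stop("series must contain at least 2 points, got ", length(x))
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop("series contains a non-finite value at position ", bad[1L])
  }
  x
}

new_visibility_graph <- function(n_nodes, edges, label = NULL) {
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, label = label),
    class = "visibility_graph"
  )
}

# canonical edge order: i < j within rows, rows lexicographic
sort_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) {
    tmp <- edges[swap, 1L]
    edges[swap, 1L] <- edges[swap, 2L]
    edges[swap, 2L] <- tmp
  }
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat("Visibility graph", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n  nodes:", x$n_nodes, "\n  edges:", nrow(x$edges),
      "\n  mean degree:", format(2 * nrow(x$edges) / x$n_nodes, digits = 4),
      "\n")
  invisible(x)
}

#' @export
as.matrix.visibility_graph <- function(x, ...) {
  a <- matrix(0L, x$n_nodes, x$n_nodes)
  a[x$edges] <- 1L
  a[x$edges[, c(2L, 1L), drop = FALSE]] <- 1L
  a
}

#' Convert a visibility graph to an igraph object
#'
#' @param graph a `visibility_graph`.
#' @return An undirected [igraph::graph] on `n_nodes` vertices.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  igraph::graph_from_edgelist(graph$edges, directed = FALSE)
}

#' Write a visibility graph as a tab-separated edge list
#'
#' One `i<TAB>j` pair per line with 0-based node indices, `i < j`, rows in
#' lexicographic order.
#'
#' @param graph a `visibility_graph`.
#' @param path output file path.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "visibility_graph"))
  write.table(graph$edges - 1L, path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tab-separated 0-based edge list back into a visibility graph
#'
#' @param path file written by [write_edgelist()].
#' @param n_nodes node count (edge lists do not record isolated trailing
#'   nodes; HVGs have none, so the default infers it from the largest index).
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  tab <- read.table(path, sep = "\t", colClasses = "integer")
  edges <- as.matrix(tab) + 1L
  dimnames(edges) <- NULL
  if (is.null(n_nodes)) n_nodes <- max(edges)
  new_visibility_graph(n_nodes, sort_edges(edges))
}

#' Write the 0/1 adjacency matrix of a visibility graph as delimited text
#'
#' @param graph a `visibility_graph`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_adjacency <- function(graph, path, sep = "\t") {
  write.table(as.matrix(graph), path, sep = sep,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
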