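#' Project a multiplex to its weighted graph of layers
#'
#' Each layer becomes one node; the weight of edge `(alpha, beta)` is the
#' interlayer degree mutual information `I_ab`. The result is by
#' construction a complete weighted graph — the visibility analogue of a
#' functional network, where weights quantify information shared between
#' channels rather than, e.g., linear correlation.
#'
#' @inheritParams interlayer_mi
#' @return An object of class `graph_of_layers`: list with `n_nodes` (= M),
#'   `weights` (symmetric matrix, zero diagonal) and `labels`.
#' @examples
#' x <- simulate_cml(cml_params(M = 5, epsilon = 0.05, N = 512, seed = 7))
#' gl <- graph_of_layers(build_multiplex(x))
#' maximum_spanning_tree(gl)$edges
#' @export
graph_of_layers <- function(mux, base = exp(1)) {
  im <- interlayer_mi_matrix(mux, base = base)
  new_graph_of_layers(im, mux$labels)
}

#' Construct a graph of layers directly from a weight matrix
#'
#' @param weights symmetric nonnegative matrix of pair weights (the
#'   diagonal is ignored).
#' @param labels optional node labels.
#' @export
new_graph_of_layers <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  M <- nrow(weights)
  if (M < 2L) stop("a graph of layers needs at least 2 layers")
  if (ncol(weights) != M || any(abs(weights - t(weights)) > 1e-12)) {
    stop("weights must be a symmetric square matrix")
  }
  diag(weights) <- 0
  if (is.null(labels)) labels <- paste0("L", seq_len(M))
  dimnames(weights) <- list(labels, labels)
  structure(list(n_nodes = M, weights = weights, labels = labels),
            class = "graph_of_layers")
}

#' @export
print.graph_of_layers <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat("Graph of layers\n  nodes:", x$n_nodes,
      "\n  weight range: [", format(min(w), digits = 4), ",",
      format(max(w), digits = 4), "]\n")
  invisible(x)
}

# all unordered pairs with their weights, lexicographic order
pair_table <- function(g) {
  M <- g$n_nodes
  idx <- which(upper.tri(g$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(a = idx[, 1L], b = idx[, 2L],
             w = g$weights[idx])
}

new_layer_subgraph <- function(g, keep, type) {
  structure(
    list(n_nodes = g$n_nodes,
         edges = as.matrix(keep[, c("a", "b")]),
         weights = keep$w,
         labels = g$labels,
         type = type),
    class = "layer_subgraph"
  )
}

subgraph_igraph <- function(sub) {
  igraph::graph_from_edgelist(sub$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, sub$n_nodes - max(sub$edges)))
}

#' Backbone of a graph of layers
#'
#' Starting from the empty graph on the M layer-nodes, edges are added in
#' decreasing weight order until the graph becomes connected. Ties are
#' resolved by threshold semantics: every edge whose weight equals the
#' connecting threshold `w_c` is included, so the output does not depend on
#' the order in which equal-weight edges are scanned. Equivalently, the
#' backbone keeps exactly the edges with weight `>= w_c`, where `w_c` is
#' the largest threshold at which the thresholded graph is connected.
#'
#' @param g a `graph_of_layers`.
#' @return A `layer_subgraph` (connected, single component) with fields
#'   `edges`, `weights`, `labels`.
#' @export
backbone <- function(g) {
  stopifnot(inherits(g, "graph_of_layers"))
  if (any(!is.finite(g$weights))) stop("backbone needs finite weights")
  pt <- pair_table(g)
  # candidate thresholds: distinct weights, high to low
  for (wc in sort(unique(pt$w), decreasing = TRUE)) {
    keep <- pt[pt$w >= wc, , drop = FALSE]
    ig <- igraph::graph_from_edgelist(as.matrix(keep[, c("a", "b")]),
                                      directed = FALSE)
    if (igraph::vcount(ig) == g$n_nodes && igraph::is_connected(ig)) {
      return(new_layer_subgraph(g, keep, "backbone"))
    }
  }
  stop("graph of layers is not connected at any threshold")
}

#' Maximum spanning tree of a graph of layers
#'
#' The spanning tree maximising total edge weight (M - 1 edges). Ties are
#' broken lexicographically on the `(alpha, beta)` pair so the result is
#' reproducible.
#'
#' @param g a `graph_of_layers`.
#' @return A `layer_subgraph` with `type = "mst"`.
#' @export
maximum_spanning_tree <- function(g) {
  stopifnot(inherits(g, "graph_of_layers"))
  pt <- pair_table(g)
  # Kruskal on negated weights via igraph; lexicographic tie-break comes
  # from the stable ordering of the edge sequence
  ord <- order(-pt$w, pt$a, pt$b)
  pt <- pt[ord, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(as.matrix(pt[, c("a", "b")]),
                                    directed = FALSE)
  igraph::E(ig)$w <- pt$w
  igraph::E(ig)$id <- seq_len(nrow(pt))
  mst <- igraph::mst(ig, weights = -igraph::E(ig)$w)
  keep <- pt[sort(igraph::E(mst)$id), , drop = FALSE]
  new_layer_subgraph(g, keep, "mst")
}

#' Topological summary of a layer subgraph
#'
#' The four descriptors used to characterise backbones across dynamical
#' phases: edge count `K`, average shortest path length `L` (unweighted,
#' mean over unordered node pairs), mean local clustering coefficient `C`
#' (unweighted; nodes of degree < 2 contribute 0), and total edge weight
#' `W`.
#'
#' @param sub a `layer_subgraph` (connected).
#' @return Named list `K`, `L`, `C`, `W`.
#' @export
summary_metrics <- function(sub) {
  stopifnot(inherits(sub, "layer_subgraph"))
  ig <- subgraph_igraph(sub)
  if (!igraph::is_connected(ig)) {
    stop("average shortest path length is undefined on a disconnected subgraph")
  }
  local_c <- igraph::transitivity(ig, type = "local", isolates = "zero")
  list(
    K = nrow(sub$edges),
    L = igraph::mean_distance(ig, directed = FALSE),
    C = mean(local_c),
    W = sum(sub$weights)
  )
}

#' Hub dominance of a spanning tree
#'
#' Maximum node degree divided by `M - 1`: 1 for a star (one layer directly
#' linked to all others, the signature of strongly synchronised epochs),
#' `1/(M-1)` for a path.
#'
#' @param tree a `layer_subgraph`, normally an MST.
#' @return A number in `(0, 1]`.
#' @export
hub_fraction <- function(tree) {
  stopifnot(inherits(tree, "layer_subgraph"))
  if (tree$n_nodes < 2L) stop("hub fraction needs at least 2 nodes")
  max(tabulate(tree$edges, nbins = tree$n_nodes)) / (tree$n_nodes - 1L)
}

#' @export
print.layer_subgraph <- function(x, ...) {
  cat("Layer subgraph (", x$type, ")\n  nodes: ", x$n_nodes,
      "\n  edges: ", nrow(x$edges),
      "\n  total weight: ", format(sum(x$weights), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Write a weighted layer graph or subgraph as an edge list
#'
#' Lines `alpha<TAB>beta<TAB>weight` using layer labels, weights at full
#' precision.
#'
#' @param x a `graph_of_layers` or `layer_subgraph`.
#' @param path output file path.
#' @export
write_layer_edges <- function(x, path) {
  if (inherits(x, "graph_of_layers")) {
    pt <- pair_table(x)
    a <- pt$a; b <- pt$b; w <- pt$w
  } else if (inherits(x, "layer_subgraph")) {
    a <- x$edges[, 1L]; b <- x$edges[, 2L]; w <- x$weights
  } else {
    stop("expected a graph_of_layers or layer_subgraph")
  }
  writeLines(paste(x$labels[a], x$labels[b],
                   format(w, digits = 17, trim = TRUE), sep = "\t"),
             path)
  invisible(path)
}
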