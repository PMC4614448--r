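#' Multiplex visibility graph of a multivariate series
#'
#' Builds one horizontal visibility graph per channel of an M-dimensional
#' signal. Layer `alpha` is exactly `build_hvg()` of channel `alpha`; all
#' layers share the node set of N time points, so the object is a multiplex
#' network represented by the vector of its layer adjacency structures.
#'
#' @param series numeric matrix (rows = time points, columns = channels)
#'   or data frame of equal-length numeric columns. Column names become
#'   layer labels.
#' @return An object of class `multiplex_vg`: list with `n_nodes`, `layers`
#'   (list of `visibility_graph`), and `labels`.
#' @examples
#' x <- simulate_cml(cml_params(M = 3, epsilon = 0.1, N = 256, seed = 1))
#' mux <- build_multiplex(x)
#' average_edge_overlap(mux)
#' mean_interlayer_mi(mux)
#' @export
build_multiplex <- function(series) {
  series <- check_multivariate(series, min_channels = 1L)
  labels <- colnames(series)
  layers <- lapply(seq_len(ncol(series)), function(a) {
    build_hvg(series[, a], label = labels[a])
  })
  new_multiplex(nrow(series), layers, labels)
}

new_multiplex <- function(n_nodes, layers, labels = NULL) {
  if (is.null(labels)) labels <- paste0("L", seq_along(layers))
  structure(
    list(n_nodes = as.integer(n_nodes), layers = layers, labels = labels),
    class = "multiplex_vg"
  )
}

#' Assemble a multiplex from pre-built layer graphs
#'
#' Mainly useful for toy examples and tests; all layers must share the same
#' node count.
#'
#' @param layers list of `visibility_graph` objects on a common node set.
#' @param labels optional layer labels.
#' @export
multiplex_from_layers <- function(layers, labels = NULL) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "visibility_graph")))
  n <- unique(vapply(layers, function(g) g$n_nodes, 1L))
  if (length(n) != 1L) stop("all layers must have the same number of nodes")
  new_multiplex(n, layers, labels)
}

#' @export
print.multiplex_vg <- function(x, ...) {
  cat("Multiplex visibility graph\n  layers:", length(x$layers),
      "\n  nodes per layer:", x$n_nodes, "\n")
  invisible(x)
}

check_multivariate <- function(series, min_channels = 2L) {
  if (is.data.frame(series)) series <- as.matrix(series)
  if (!is.matrix(series) || !is.numeric(series)) {
    stop("expected a numeric matrix with rows = time points, columns = channels")
  }
  if (ncol(series) < min_channels) {
    stop("need at least ", min_channels, " channel(s), got ", ncol(series))
  }
  if (nrow(series) < 2L) stop("channels must contain at least 2 time points")
  series
}

# integer keys identifying the edges of one layer within a common node set;
# each stored edge contributes exactly one key (the O(N x M) contract)
edge_keys <- function(graph) {
  (graph$edges[, 1L] - 1) * graph$n_nodes + graph$edges[, 2L]
}

#' Average edge overlap of a multiplex
#'
#' The mean, over the union edge set of all layers, of the fraction of
#' layers in which an edge is present:
#' \deqn{\omega = \frac{\sum_{i<j}\sum_\alpha a_{ij}^{[\alpha]}}
#'   {M \sum_{i<j} \left(1 - \delta_{0,\sum_\alpha a_{ij}^{[\alpha]}}\right)}}
#' `M * omega` is the expected number of layers carrying a randomly chosen
#' union edge. `omega` ranges over `[1/M, 1]`: it equals `1/M` when every
#' union edge lives in exactly one layer and 1 only when all layers are
#' identical, so it acts as a proxy for the overall coherence of the
#' original multichannel signal. The computation touches each stored edge
#' once, i.e. O(N x M) for sparse visibility layers.
#'
#' @param mux a `multiplex_vg`.
#' @return A single number in `[1/M, 1]`.
#' @export
average_edge_overlap <- function(mux) {
  stopifnot(inherits(mux, "multiplex_vg"))
  keys <- unlist(lapply(mux$layers, edge_keys), use.names = FALSE)
  if (length(keys) == 0L) {
    stop("average edge overlap is undefined: the union edge set is empty")
  }
  n_union <- length(unique(keys))
  length(keys) / (length(mux$layers) * n_union)
}

#' Joint degree distribution of two layers
#'
#' Tabulates, over the shared nodes, the pairs (degree in layer `alpha`,
#' degree in layer `beta`). The counts sum to N and their row/column
#' marginals reproduce the single-layer degree counts exactly.
#'
#' @param mux a `multiplex_vg`.
#' @param alpha,beta layer indices (1-based).
#' @return An object of class `joint_degree_distribution`: list with
#'   `counts` (data frame `k_alpha`, `k_beta`, `n`), `n_nodes`, `layers`.
#' @export
joint_degree_distribution <- function(mux, alpha, beta) {
  deg <- layer_degrees(mux, c(alpha, beta))
  tab <- table(k_alpha = deg[[1L]], k_beta = deg[[2L]])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  counts <- data.frame(
    k_alpha = as.integer(df$k_alpha),
    k_beta = as.integer(df$k_beta),
    n = as.integer(df$Freq)
  )
  counts <- counts[order(counts$k_alpha, counts$k_beta), , drop = FALSE]
  rownames(counts) <- NULL
  structure(
    list(counts = counts, n_nodes = mux$n_nodes,
         layers = c(alpha, beta)),
    class = "joint_degree_distribution"
  )
}

layer_degrees <- function(mux, idx) {
  stopifnot(inherits(mux, "multiplex_vg"))
  M <- length(mux$layers)
  if (any(idx < 1L | idx > M)) {
    stop("layer index out of range 1..", M)
  }
  lapply(idx, function(a) degree_sequence(mux$layers[[a]]))
}

#' Interlayer degree mutual information of two layers
#'
#' Plug-in (maximum-likelihood) mutual information between the degree
#' sequences of layers `alpha` and `beta`, computed from the node-wise
#' joint degree distribution:
#' \deqn{I_{\alpha\beta} = \sum_{k^{[\alpha]}}\sum_{k^{[\beta]}}
#'   P(k^{[\alpha]}, k^{[\beta]})
#'   \log\frac{P(k^{[\alpha]}, k^{[\beta]})}
#'            {P(k^{[\alpha]})\,P(k^{[\beta]})}}
#' with the convention `0 log 0 = 0` and no bias correction. Symmetric in
#' the two layers and nonnegative; for `alpha == beta` it equals the
#' Shannon entropy of the layer's degree distribution. Higher values mean
#' more strongly correlated layer microstructure, hence more information
#' shared between the corresponding channels.
#'
#' @param mux a `multiplex_vg`.
#' @param alpha,beta layer indices (1-based); `alpha == beta` is allowed.
#' @param base logarithm base; the default `exp(1)` reports nats, use 2
#'   for bits. All in-package comparisons are base-invariant.
#' @return A nonnegative number.
#' @export
interlayer_mi <- function(mux, alpha, beta, base = exp(1)) {
  deg <- layer_degrees(mux, c(alpha, beta))
  discrete_mi(deg[[1L]], deg[[2L]], base = base)
}

# plug-in MI of two aligned integer sequences
discrete_mi <- function(a, b, base = exp(1)) {
  n <- length(a)
  stopifnot(length(b) == n)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(pa, pb)
  sum(joint[nz] * log(joint[nz] / outer_p[nz], base = base))
}

#' Mean interlayer mutual information of a multiplex
#'
#' Unweighted mean of [interlayer_mi()] over the `M(M-1)/2` unordered layer
#' pairs; the scalar order parameter summarising the typical information
#' flow among channels.
#'
#' @inheritParams interlayer_mi
#' @return A nonnegative number.
#' @export
mean_interlayer_mi <- function(mux, base = exp(1)) {
  im <- interlayer_mi_matrix(mux, base = base)
  mean(im[upper.tri(im)])
}

#' Full matrix of pairwise interlayer mutual information
#'
#' @inheritParams interlayer_mi
#' @param diagonal if `TRUE`, fill the diagonal with each layer's degree
#'   entropy (`I_aa`); otherwise leave zeros.
#' @return Symmetric `M x M` matrix with layer labels on both dimnames.
#' @export
interlayer_mi_matrix <- function(mux, base = exp(1), diagonal = FALSE) {
  stopifnot(inherits(mux, "multiplex_vg"))
  M <- length(mux$layers)
  if (M < 2L) stop("interlayer mutual information needs at least 2 layers")
  degs <- lapply(mux$layers, degree_sequence)
  im <- matrix(0, M, M, dimnames = list(mux$labels, mux$labels))
  for (a in seq_len(M - 1L)) {
    for (b in (a + 1L):M) {
      im[a, b] <- im[b, a] <- discrete_mi(degs[[a]], degs[[b]], base = base)
    }
  }
  if (diagonal) {
    for (a in seq_len(M)) im[a, a] <- discrete_mi(degs[[a]], degs[[a]], base = base)
  }
  im
}

#' One-call multiplex summary
#'
#' @inheritParams interlayer_mi
#' @return List with `omega` (average edge overlap), `I` (mean interlayer
#'   mutual information) and `I_matrix` (the pairwise matrix).
#' @export
multiplex_metrics <- function(mux, base = exp(1)) {
  im <- interlayer_mi_matrix(mux, base = base)
  list(
    omega = average_edge_overlap(mux),
    I = mean(im[upper.tri(im)]),
    I_matrix = im
  )
}

#' Write a multiplex as per-layer edge lists plus a manifest
#'
#' Produces `<stem>-<label>.edges` (one per layer, [write_edgelist()]
#' format), a combined three-column `<stem>.layers` file with lines
#' `layer<TAB>i<TAB>j`, and a `<stem>.manifest` mapping labels to files.
#'
#' @param mux a `multiplex_vg`.
#' @param stem path prefix for the output files.
#' @return Invisibly, the manifest path.
#' @export
write_multiplex <- function(mux, stem) {
  stopifnot(inherits(mux, "multiplex_vg"))
  files <- character(length(mux$layers))
  for (a in seq_along(mux$layers)) {
    files[a] <- paste0(stem, "-", mux$labels[a], ".edges")
    write_edgelist(mux$layers[[a]], files[a])
  }
  combined <- do.call(rbind, lapply(seq_along(mux$layers), function(a) {
    e <- mux$layers[[a]]$edges
    data.frame(layer = mux$labels[a], i = e[, 1L] - 1L, j = e[, 2L] - 1L)
  }))
  write.table(combined, paste0(stem, ".layers"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  manifest <- paste0(stem, ".manifest")
  writeLines(paste(mux$labels, basename(files), sep = "\t"), manifest)
  invisible(manifest)
}

#' Write multiplex metrics as delimited key/value text
#'
#' Emits `omega`, `I`, and the upper triangle of the pairwise mutual
#' information matrix as `I[a,b]` keys, one `key<TAB>value` line each,
#' floats at full precision.
#'
#' @inheritParams interlayer_mi
#' @param path output file path.
#' @export
write_metrics <- function(mux, path, base = exp(1)) {
  m <- multiplex_metrics(mux, base = base)
  M <- nrow(m$I_matrix)
  keys <- c("omega", "I")
  vals <- c(m$omega, m$I)
  for (a in seq_len(M - 1L)) {
    for (b in (a + 1L):M) {
      keys <- c(keys, sprintf("I[%s,%s]", mux$labels[a], mux$labels[b]))
      vals <- c(vals, m$I_matrix[a, b])
    }
  }
  writeLines(paste(keys, format(vals, digits = 17, trim = TRUE), sep = "\t"),
             path)
  invisible(path)
}
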