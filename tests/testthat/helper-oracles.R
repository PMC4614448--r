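# Independent brute-force oracles used to validate the package's
# constructions. These deliberately implement the defining criteria by
# direct enumeration (quadratic or worse) and share no code with the
# package internals.

# horizontal visibility by definition: (i, j) linked iff every intermediate
# value is strictly below min(x[i], x[j])
brute_hvg_edges <- function(x) {
  n <- length(x)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      between <- if (j - i > 1L) x[(i + 1L):(j - 1L)] else numeric(0)
      if (all(between < min(x[i], x[j]))) {
        ei <- c(ei, i); ej <- c(ej, j)
      }
    }
  }
  cbind(ei, ej, deparse.level = 0)
}

# natural visibility by definition: intermediates strictly below the chord
brute_nvg_edges <- function(x) {
  n <- length(x)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- TRUE
      if (j - i > 1L) {
        for (k in (i + 1L):(j - 1L)) {
          chord <- x[i] + (x[j] - x[i]) * (k - i) / (j - i)
          if (x[k] >= chord) { ok <- FALSE; break }
        }
      }
      if (ok) { ei <- c(ei, i); ej <- c(ej, j) }
    }
  }
  cbind(ei, ej, deparse.level = 0)
}

edge_key_string <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  i <- pmin(edges[, 1L], edges[, 2L])
  j <- pmax(edges[, 1L], edges[, 2L])
  sort(paste(i, j, sep = "-"))
}

# maximum spanning tree weight by exhaustive enumeration of all
# (M - 1)-edge subsets; feasible for M <= 6
brute_max_spanning_weight <- function(w) {
  M <- nrow(w)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  best <- -Inf
  for (subset in utils::combn(nrow(pairs), M - 1L, simplify = FALSE)) {
    ig <- igraph::graph_from_edgelist(pairs[subset, , drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ig) == M && igraph::is_connected(ig)) {
      best <- max(best, sum(w[pairs[subset, , drop = FALSE]]))
    }
  }
  best
}

# plug-in mutual information by direct summation over the observed joint
# table, written independently of the package's vectorised version
brute_mi <- function(a, b, base = exp(1)) {
  n <- length(a)
  total <- 0
  for (ka in unique(a)) {
    for (kb in unique(b)) {
      pab <- sum(a == ka & b == kb) / n
      if (pab > 0) {
        total <- total + pab * log(pab / ((sum(a == ka) / n) * (sum(b == kb) / n)),
                                   base = base)
      }
    }
  }
  total
}

# random weighted complete graph on M nodes
random_graph_of_layers <- function(M, ties = FALSE) {
  w <- matrix(0, M, M)
  vals <- if (ties) sample(1:4, M * (M - 1) / 2, replace = TRUE) else
    runif(M * (M - 1) / 2)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  new_graph_of_layers(w)
}

# crossing-edge check: HVGs must be outerplanar on the time line
has_crossing <- function(edges) {
  m <- nrow(edges)
  if (m < 2L) return(FALSE)
  for (e in seq_len(m - 1L)) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    f <- (e + 1L):m
    if (any(i < edges[f, 1L] & edges[f, 1L] < j & j < edges[f, 2L])) {
      return(TRUE)
    }
  }
  FALSE
}
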