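#' Temporal multiplex from non-overlapping windows
#'
#' Splits a long multichannel series into consecutive non-overlapping
#' windows of fixed length and builds one multiplex visibility graph per
#' window — the structure used to track slowly evolving coordination in
#' long recordings (e.g. quarterly snapshots of a basket of asset prices).
#' A trailing partial window is dropped. Visibility requires a gapless
#' ordered index, so windows containing missing values are rejected rather
#' than imputed; pre-clean the input.
#'
#' @param series numeric matrix (rows = time, columns = channels).
#' @param window_length number of time points per window, at least 2.
#' @return An object of class `temporal_multiplex`: list with `snapshots`
#'   (list of `multiplex_vg`), `window_bounds` (matrix of 1-based
#'   `[start, end]` row indices) and `labels`.
#' @examples
#' x <- simulate_cml(cml_params(M = 3, epsilon = 0.1, N = 600, seed = 1))
#' tm <- windowed_multiplex(x, 200)
#' temporal_profiles(tm)
#' @export
windowed_multiplex <- function(series, window_length) {
  series <- check_multivariate(series, min_channels = 1L)
  window_length <- as.integer(window_length)
  if (window_length < 2L) stop("window_length must be at least 2")
  n_win <- nrow(series) %/% window_length
  if (n_win < 1L) stop("series shorter than one window")
  snapshots <- vector("list", n_win)
  bounds <- matrix(0L, n_win, 2L, dimnames = list(NULL, c("start", "end")))
  for (w in seq_len(n_win)) {
    start <- (w - 1L) * window_length + 1L
    end <- w * window_length
    snapshots[[w]] <- build_multiplex(series[start:end, , drop = FALSE])
    bounds[w, ] <- c(start, end)
  }
  structure(
    list(snapshots = snapshots, window_bounds = bounds,
         labels = paste0("w", seq_len(n_win))),
    class = "temporal_multiplex"
  )
}

#' Per-window multiplex metrics
#'
#' One row per snapshot: average edge overlap, mean interlayer mutual
#' information, the hub fraction of the maximum spanning tree of the graph
#' of layers, and the MST total weight. Peaks of `omega` and `I` flag
#' windows of increased cross-channel synchronisation; a hub fraction near
#' one means a single channel dominates the tree.
#'
#' @param tm a `temporal_multiplex` whose snapshots have at least 2 layers.
#' @param base logarithm base for the mutual information.
#' @return Data frame with columns `window`, `start`, `end`, `omega`, `I`,
#'   `hub_fraction`, `mst_weight`.
#' @export
temporal_profiles <- function(tm, base = exp(1)) {
  stopifnot(inherits(tm, "temporal_multiplex"))
  rows <- lapply(seq_along(tm$snapshots), function(w) {
    mux <- tm$snapshots[[w]]
    gl <- graph_of_layers(mux, base = base)
    mst <- maximum_spanning_tree(gl)
    data.frame(
      window = tm$labels[w],
      start = tm$window_bounds[w, 1L],
      end = tm$window_bounds[w, 2L],
      omega = average_edge_overlap(mux),
      I = mean_interlayer_mi(mux, base = base),
      hub_fraction = hub_fraction(mst),
      mst_weight = sum(mst$weights)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centered running average with truncated ends
#'
#' Smooths a profile with a centered moving mean of half-width `h`
#' (window `2h + 1`), truncating the window where it overruns the ends.
#' `h = 0` returns the input unchanged.
#'
#' @param x numeric vector.
#' @param half_width nonnegative integer half-width, in samples (windows).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' running_average(c(0, 0, 1, 0, 0), 1)
#' @export
running_average <- function(x, half_width = 2L) {
  half_width <- as.integer(half_width)
  stopifnot(half_width >= 0L)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Piecewise coupled-map-lattice series with switching coupling
#'
#' Concatenates lattice runs whose coupling strength changes between
#' segments, carrying the lattice state across the boundaries (only the
#' first segment discards a transient). This emulates a system moving
#' between dynamical regimes — e.g. quiet versus synchronised epochs —
#' with known ground truth, for validating windowed analyses.
#'
#' @param segments list of segments, each a list (or named vector) with
#'   `epsilon` and `length`; zero-length segments are skipped.
#' @param M number of sites shared by all segments.
#' @param transient initial discarded steps before the first segment.
#' @param topology `"ring"` or `"chain"`.
#' @param map local map.
#' @param seed RNG seed for the initial state.
#' @return Numeric matrix (total length x M) with a `"regime"` attribute:
#'   integer vector labelling each recorded row with its segment number.
#' @examples
#' x <- make_regime_series(
#'   list(list(epsilon = 0.05, length = 512),
#'        list(epsilon = 0.17, length = 512)),
#'   M = 5, seed = 3)
#' table(attr(x, "regime"))
#' @export
make_regime_series <- function(segments, M, transient = 1000L,
                               topology = c("ring", "chain"),
                               map = logistic_map, seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(length(segments) >= 1L, M >= 2L)
  lens <- vapply(segments, function(s) as.integer(s[["length"]]), 1L)
  eps <- vapply(segments, function(s) as.numeric(s[["epsilon"]]), 1)
  keep <- lens > 0L
  lens <- lens[keep]; eps <- eps[keep]
  if (length(lens) == 0L) stop("all segments have zero length")
  if (any(eps < 0 | eps > 1)) stop("epsilon must lie in [0, 1]")

  if (!is.null(seed)) set.seed(seed)
  M <- as.integer(M)
  left <- c(M, seq_len(M - 1L))
  right <- c(seq_len(M - 1L) + 1L, 1L)
  if (topology == "chain") {
    left[1L] <- 2L
    right[M] <- M - 1L
  }
  x <- runif(M)
  step <- function(x, e) {
    fx <- map(x)
    (1 - e) * fx + (e / 2) * (fx[left] + fx[right])
  }
  for (t in seq_len(as.integer(transient))) x <- step(x, eps[1L])

  out <- matrix(0, sum(lens), M,
                dimnames = list(NULL, paste0("s", seq_len(M))))
  regime <- integer(sum(lens))
  row <- 0L
  for (s in seq_along(lens)) {
    for (t in seq_len(lens[s])) {
      x <- step(x, eps[s])
      row <- row + 1L
      out[row, ] <- x
      regime[row] <- s
    }
  }
  attr(out, "regime") <- regime
  out
}
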