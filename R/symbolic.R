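#' Symbolize a series by a fixed equal-width partition
#'
#' Coarse-grains a real-valued series into `p` symbols by splitting
#' `[lo, hi]` into `p` equal-width bins. Bins are half-open
#' `[lo + (m-1)*d, lo + m*d)` except the last, which is closed at `hi`
#' (so `hi` itself maps to symbol `p`). This fixed-partition scheme is the
#' standard pre-processing step of symbolization-based functional-network
#' analysis; its sensitivity to the choice of `p` and of the range is
#' precisely the ambiguity that the visibility multiplex avoids.
#'
#' @param x numeric vector with all values inside `range`.
#' @param p alphabet size, at least 2.
#' @param range length-2 numeric `c(lo, hi)`; the default unit interval
#'   matches the state space of the coupled-map-lattice simulator. Use
#'   `range = NULL` for the per-series observed `[min, max]`.
#' @return An object of class `symbolic_series`: integer vector of symbols
#'   in `1..p` with attributes `p` and `breaks`.
#' @examples
#' symbolize(c(0.1, 0.5, 0.99, 1.0), p = 2)
#' @export
symbolize <- function(x, p = 2L, range = c(0, 1)) {
  x <- as.numeric(x)
  stopifnot(p >= 2L)
  if (is.null(range)) range <- c(min(x), max(x))
  lo <- range[1L]; hi <- range[2L]
  if (!(lo < hi)) stop("range must satisfy lo < hi")
  bad <- which(x < lo | x > hi | !is.finite(x))
  if (length(bad) > 0L) {
    stop("datum at position ", bad[1L], " falls outside [", lo, ", ", hi, "]")
  }
  s <- pmin(as.integer(floor((x - lo) / (hi - lo) * p)) + 1L, as.integer(p))
  structure(s, p = as.integer(p),
            breaks = seq(lo, hi, length.out = p + 1L),
            class = "symbolic_series")
}

#' Mutual information between two symbol sequences
#'
#' Plug-in mutual information of the empirical joint symbol distribution
#' over aligned time points, with `0 log 0 = 0`. Bounded above by
#' `log(p)` in the chosen base.
#'
#' @param a,b `symbolic_series` (or plain integer vectors) of equal length.
#' @param base logarithm base (natural log by default, matching the
#'   interlayer mutual information).
#' @return A nonnegative number.
#' @export
symbolic_mi <- function(a, b, base = exp(1)) {
  if (length(a) != length(b)) stop("symbol sequences must have equal length")
  discrete_mi(as.integer(a), as.integer(b), base = base)
}

#' Mean pairwise symbolic mutual information of a multivariate series
#'
#' The symbolization-based baseline: symbolize each channel with the same
#' partition, then average [symbolic_mi()] over all unordered channel
#' pairs. Comparable to [mean_interlayer_mi()] computed on the visibility
#' multiplex of the same data.
#'
#' @param series numeric matrix (rows = time, columns = channels), M >= 2.
#' @param p alphabet size.
#' @param range partition range passed to [symbolize()]; `NULL` for
#'   per-channel observed ranges.
#' @param base logarithm base.
#' @return A nonnegative number.
#' @export
mean_symbolic_mi <- function(series, p = 2L, range = c(0, 1),
                             base = exp(1)) {
  series <- check_multivariate(series, min_channels = 2L)
  M <- ncol(series)
  syms <- lapply(seq_len(M), function(a) symbolize(series[, a], p, range))
  vals <- numeric(0)
  for (a in seq_len(M - 1L)) {
    for (b in (a + 1L):M) {
      vals <- c(vals, symbolic_mi(syms[[a]], syms[[b]], base = base))
    }
  }
  mean(vals)
}

#' @export
print.symbolic_series <- function(x, ...) {
  cat("Symbolic series\n  length:", length(x),
      "\n  alphabet size:", attr(x, "p"), "\n")
  invisible(x)
}
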