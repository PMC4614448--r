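#' Fully chaotic logistic map
#'
#' `f(x) = 4 x (1 - x)` on the unit interval, the default local dynamics of
#' the coupled-map-lattice simulator.
#'
#' @param x numeric in `[0, 1]` (vectorised).
#' @return `4 * x * (1 - x)`.
#' @export
logistic_map <- function(x) {
  if (any(x < 0 | x > 1)) stop("logistic map is defined on [0, 1]")
  4 * x * (1 - x)
}

#' Parameters of a coupled map lattice run
#'
#' Bundles the knobs of the simulator. The dynamics couples `M` chaotic
#' maps diffusively:
#' \deqn{x^{[\alpha]}_{t+1} = (1-\varepsilon) f(x^{[\alpha]}_t) +
#'   \frac{\varepsilon}{2}\left[f(x^{[\alpha-1]}_t) +
#'   f(x^{[\alpha+1]}_t)\right]}
#' with periodic site indices on a ring, reflecting ends on a chain, and a
#' mean-field (`epsilon/M` times the sum over all sites) coupling for the
#' globally coupled variant. The coupling strength `epsilon` tunes the
#' diffusive term and drives the lattice through its dynamical phases —
#' fully developed turbulence (FDT), brownian motion of defects (BD),
#' spatio-temporal intermittency (STI), periodic pattern selection (PS) —
#' as it varies over `[0, 1]`.
#'
#' @param M number of sites (channels), at least 2.
#' @param epsilon coupling strength in `[0, 1]`.
#' @param N recorded length after the transient.
#' @param transient discarded initial steps; the default `1000` is ample
#'   for the logistic lattice to reach its attractor.
#' @param topology `"ring"` (periodic), `"chain"` (reflecting ends) or
#'   `"global"` (mean field).
#' @param map local map, a vectorised function on `[0, 1]`.
#' @param seed RNG seed for the i.i.d. uniform(0, 1) initial state; `NULL`
#'   uses the current RNG state.
#' @param x0 optional explicit initial state (length `M`, values in
#'   `[0, 1]`); overrides the random initial conditions. Useful for
#'   studying the invariant synchronised manifold.
#' @return An object of class `cml_params`.
#' @export
cml_params <- function(M, epsilon, N, transient = 1000L,
                       topology = c("ring", "chain", "global"),
                       map = logistic_map, seed = NULL, x0 = NULL) {
  topology <- match.arg(topology)
  stopifnot(M >= 2L, N >= 2L, transient >= 0L)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (!is.null(x0)) {
    stopifnot(length(x0) == M, all(x0 >= 0 & x0 <= 1))
  }
  structure(
    list(M = as.integer(M), epsilon = epsilon, N = as.integer(N),
         transient = as.integer(transient), topology = topology,
         map = map, seed = seed, x0 = x0),
    class = "cml_params"
  )
}

#' Simulate a diffusively coupled map lattice
#'
#' Iterates the lattice from i.i.d. uniform(0, 1) initial conditions,
#' discards the transient, and records `N` steps per site. The update is a
#' convex combination of map values, so the state stays in `[0, 1]`, and
#' the synchronised manifold (all sites equal) is invariant.
#'
#' @param params a [cml_params()] object with `topology` `"ring"` or
#'   `"chain"` (use [simulate_gcm()] for `"global"`).
#' @return Numeric `N x M` matrix (rows = time, columns = sites), with
#'   column names `s1..sM` and the parameters attached as attribute
#'   `"params"`.
#' @examples
#' x <- simulate_cml(cml_params(M = 5, epsilon = 0.17, N = 1024, seed = 42))
#' mux <- build_multiplex(x)
#' c(omega = average_edge_overlap(mux), I = mean_interlayer_mi(mux))
#' @export
simulate_cml <- function(params) {
  stopifnot(inherits(params, "cml_params"))
  if (!params$topology %in% c("ring", "chain")) {
    stop("simulate_cml handles ring/chain topologies; use simulate_gcm for global coupling")
  }
  M <- params$M
  left <- c(M, seq_len(M - 1L))   # alpha - 1, periodic
  right <- c(seq_len(M - 1L) + 1L, 1L)
  if (params$topology == "chain") {
    # reflecting ends: the missing neighbour mirrors the inner one
    left[1L] <- 2L
    right[M] <- M - 1L
  }
  run_lattice(params, function(fx) {
    (1 - params$epsilon) * fx + (params$epsilon / 2) * (fx[left] + fx[right])
  })
}

#' Simulate globally coupled maps
#'
#' Mean-field variant: every site is coupled with strength `epsilon/M` to
#' the map value of every site (including itself). Complete
#' synchronisation is possible here: at large `epsilon` all sites collapse
#' onto a single chaotic orbit, and at `epsilon = 1` they are identical
#' from the first step onward.
#'
#' @param params a [cml_params()] object with `topology = "global"`.
#' @inherit simulate_cml return
#' @export
simulate_gcm <- function(params) {
  stopifnot(inherits(params, "cml_params"))
  if (params$topology != "global") {
    stop("simulate_gcm requires topology = \"global\"")
  }
  eps <- params$epsilon
  M <- params$M
  run_lattice(params, function(fx) {
    (1 - eps) * fx + (eps / M) * sum(fx)
  })
}

run_lattice <- function(params, update) {
  if (!is.null(params$seed)) set.seed(params$seed)
  x <- if (!is.null(params$x0)) as.numeric(params$x0) else runif(params$M)
  f <- params$map
  for (t in seq_len(params$transient)) x <- update(f(x))
  out <- matrix(0, params$N, params$M,
                dimnames = list(NULL, paste0("s", seq_len(params$M))))
  for (t in seq_len(params$N)) {
    x <- update(f(x))
    out[t, ] <- x
  }
  attr(out, "params") <- params
  out
}

#' Sweep the coupling strength and record multiplex metrics
#'
#' For each value of `epsilon`, runs independent seeded realizations of the
#' lattice, builds the multiplex visibility graph of each, computes the
#' average edge overlap and mean interlayer mutual information per
#' realization, and reports per-epsilon means with standard errors.
#'
#' @param eps_grid numeric vector of coupling strengths in `[0, 1]`.
#' @param M,N,transient,topology,map passed to [cml_params()].
#' @param n_realizations independent runs per grid point.
#' @param seed master seed; per-realization seeds are drawn from it so the
#'   whole sweep is reproducible.
#' @param base logarithm base for the mutual information.
#' @param metrics which descriptors to record. Mean interlayer mutual
#'   information is quadratic in `M` (all layer pairs), so large-lattice
#'   overlap sweeps should request `"omega"` only.
#' @return Data frame with one row per `epsilon`: `epsilon`, the requested
#'   metric means with standard errors, and `n_realizations`.
#' @export
cml_sweep <- function(eps_grid, M, N, n_realizations = 10L,
                      transient = 1000L, topology = "ring",
                      map = logistic_map, seed = NULL, base = exp(1),
                      metrics = c("omega", "I")) {
  stopifnot(all(eps_grid >= 0 & eps_grid <= 1), n_realizations >= 1L)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(eps_grid) * n_realizations)
  dim(seeds) <- c(length(eps_grid), n_realizations)
  rows <- lapply(seq_along(eps_grid), function(g) {
    om <- numeric(n_realizations)
    mi <- numeric(n_realizations)
    for (r in seq_len(n_realizations)) {
      p <- cml_params(M = M, epsilon = eps_grid[g], N = N,
                      transient = transient, topology = topology,
                      map = map, seed = seeds[g, r])
      x <- if (topology == "global") simulate_gcm(p) else simulate_cml(p)
      mux <- build_multiplex(x)
      if ("omega" %in% metrics) om[r] <- average_edge_overlap(mux)
      if ("I" %in% metrics) mi[r] <- mean_interlayer_mi(mux, base = base)
    }
    row <- data.frame(epsilon = eps_grid[g])
    if ("omega" %in% metrics) {
      row$omega <- mean(om)
      row$omega_se <- sd(om) / sqrt(n_realizations)
    }
    if ("I" %in% metrics) {
      row$I <- mean(mi)
      row$I_se <- sd(mi) / sqrt(n_realizations)
    }
    row$n_realizations <- n_realizations
    row
  })
  do.call(rbind, rows)
}
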