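---
title: "Multiplex visibility graph analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex visibility graph analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhvg)
```

## The method

An M-dimensional signal `x^[α](t)`, `α = 1..M`, `t = 1..N`, is mapped to an
M-layer multiplex network. Layer `α` is the horizontal visibility graph
(HVG) of channel `α`: nodes are the N time points, and `i < j` are linked
iff every intermediate datum satisfies the strict ordering relation
`x(k) < min(x(i), x(j))`. Every HVG contains the path
`(1,2), (2,3), ...` (adjacent points always see each other), is connected,
and is outerplanar — no two edges cross when the nodes sit on the time
line. Because all layers share the node set, multiplex descriptors apply
directly:

* **Average edge overlap** `ω`: the mean, over the union edge set, of the
  fraction of layers carrying the edge. `ω ∈ [1/M, 1]`; the lower bound is
  attained when every union edge lives in exactly one layer, the upper
  bound only when all layers are identical. Since each stored edge is
  touched once, the cost is `O(N·M)` for visibility layers (which are
  sparse: at most `2N − 3` edges per layer).
* **Interlayer degree mutual information** `I_αβ`: plug-in mutual
  information between the degree sequences of layers `α` and `β`, from the
  node-wise joint degree table. The joint counts sum to `N` and
  marginalise exactly to the per-layer degree counts, an identity the test
  suite asserts on random multiplexes. The scalar `I` is the unweighted
  mean of `I_αβ` over the `M(M−1)/2` unordered pairs.

The matrix `{I_αβ}` defines the weighted, complete **graph of layers** —
a functional network obtained without symbolizing the series. Two
summaries compress it: the **backbone** (add edges in decreasing weight
until one connected component remains) and the **maximum spanning tree**
(M − 1 edges of maximum total weight), described by edge count `K`,
unweighted mean shortest path `L`, mean local clustering `C`, total
weight `W`, and the MST hub fraction (max degree over `M − 1`).

### Assumptions

Visibility is defined on a gapless, ordered index. Channels must be
finite, equal-length, and aligned; missing data are rejected, not imputed.
The method is invariant to channel-wise monotone rescaling of the values
(visibility depends only on order relations within each channel), which is
what makes it robust against the partition choices that symbolization
requires.

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| log base | all MI | natural (nats) | no base is canonical; rankings, backbones and MSTs are base-invariant. `base = 2` gives bits. |
| tie rule | HVG | strict blocking | an intermediate equal to the smaller endpoint blocks visibility, following the strict ordering relation. Ties never occur for continuous-state chaos but dominate quantized data; the convention is therefore explicit, not incidental. |
| backbone ties | layer graph | threshold semantics | all edges at the connecting weight `w_c` are included, making the output independent of scan order. The sequential "add until connected" description is ambiguous under ties; threshold semantics is the deterministic reading, and it preserves MST ⊆ backbone. |
| `p`, partition range | symbolic baseline | `p = 2`, range `[0, 1]` | the two-symbol equal-width partition on the known lattice state space; `p = 6` is the stock alternative. For empirical data the per-channel `[min, max]` range is available — the sensitivity to this very choice is the baseline's documented weakness. |
| window length | temporal analysis | caller-chosen | windows are non-overlapping, remainder dropped; the running-average smoother defaults to half-width 2 windows. |

## The lattice generator

`simulate_cml()` iterates `x_{t+1}^[α] = (1−ε)·f(x_t^[α]) +
(ε/2)·[f(x_t^[α−1]) + f(x_t^[α+1])]` with `f(x) = 4x(1−x)`, periodic
indices on a ring (reflecting ends on a chain), i.i.d. uniform(0,1)
initial conditions, and a discarded transient; `simulate_gcm()` replaces
the neighbour term with the mean field `(ε/M)·Σ_β f(x_t^[β])`. The update
is a convex combination of values of `f` on `[0, 1]`, so the state stays
in the unit interval, and the synchronised manifold is invariant — both
property-tested. With `M = 2` the mean-field update at coupling `ε`
equals the ring update at `ε/2`, an algebraic identity the tests verify
through the public interface.

Design choices where the canon leaves room:

* **Update form.** The diffusive (Kaneko) coupling above is the canonical
  nearest-neighbour Laplacian form for a ring of locally chaotic maps.
* **Boundary condition.** Ring (periodic) is the default everywhere,
  including at `M = 200`; `chain` is offered. In the bulk statistics the
  two differ little (the overlap sweep gives the same phase picture for
  both), so the choice is not load-bearing.
* **Transient.** 10^3 discarded steps. This is ample for the turbulent
  phases. In the pattern-selection window the approach to the periodic
  attractor is slow and realization-dependent, so ensemble means of
  overlap there retain a dependence on the transient convention: runs
  that have fully locked onto the periodic pattern carry several times
  the overlap of runs still en route. The transient is a declared
  generator constant, fixed once; per-realization standard errors are
  reported by `cml_sweep()` so this spread is visible rather than hidden.
* **Initial conditions.** i.i.d. uniform(0,1) from a caller seed; an
  explicit `x0` override exists for studying invariant manifolds.
* **Replicates.** `cml_sweep()` supports any replicate count and reports
  standard errors; the shipped analyses use 5–10 realizations per grid
  point with `N = 2^14` recorded steps — sizes chosen so the full suite
  re-runs comfortably on a laptop while leaving the phase contrasts many
  standard errors wide.

### What the generator does and does not emulate

The lattice provides ground truth for *relative* statements: overlap and
interlayer information must rise from the turbulent to the
pattern-selection phase, the weak-coupling graph of layers must recover
the ring wiring, windowed profiles must rank a strongly coupled segment
above a weakly coupled one. Passing these tests shows the pipeline
detects coordination structure in signals with known coupling. It does
not show robustness to trends, heteroscedastic noise, quantization,
missing data or channel misalignment — all common in empirical
recordings and all outside what the lattice produces. The temporal
machinery mirrors the windowed-snapshot design used for long financial
recordings, but no real financial data is packaged; the regime-switching
generator (`make_regime_series()`) is a synthetic stand-in with labelled
segments.

## Numerical choices

* The HVG builder is a single-pass monotone-stack algorithm in C++
  (expected linear on noisy input, quadratic worst case on monotone
  input); its contract is exact agreement with the brute-force
  `O(N²)` criterion check, enforced on random series with and without
  ties (N up to 512, 100 series).
* Mutual information uses raw maximum-likelihood estimates with
  `0·log 0 = 0` and no bias correction — the estimator is part of the
  method's definition here, and all comparisons are within like-sized
  samples. The plug-in bias (order `(p−1)²/2N` nats for a `p`-symbol
  alphabet) is why the independent-channel baseline test allows a small
  positive value at `N = 2^14`.
* Joint degree tables are sparse tabulations over observed degree pairs;
  HVG degrees are unbounded in principle.
* MST ties are broken lexicographically on the layer pair; the backbone's
  threshold semantics guarantees it contains every MST (the MST's minimum
  edge weight equals the connectivity threshold), checked exhaustively
  for `M ≤ 6` and on random weighted graphs.
* `L` and `C` are computed on the unweighted topology of a subgraph;
  weighted variants are deliberately not offered for these summaries.
* Degenerate inputs: series of length 2 give the single-edge graph;
  an empty union edge set makes `ω` undefined (error, not NA); `M = 1`
  multiplexes are valid containers but refuse pairwise metrics.

## Limitations

* Directed/weighted visibility variants and time-irreversibility measures
  are out of scope; the natural (convexity) visibility constructor is
  provided as an extra but none of the multiplex metrics depend on it.
* The plug-in MI estimator is biased upward at small `N`; window lengths
  below a few hundred points make `I` profiles noisy (the windowed-variance
  test documents the shrinkage with window length).
* Pattern-selection ensemble averages depend on the transient convention
  (above); comparisons across studies should fix and report it.
* Calendar alignment, return transformations and other preprocessing for
  empirical data are upstream of this package: the input contract is a
  clean rectangular numeric table.
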