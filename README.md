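# mhvg — multiplex horizontal visibility graphs for multivariate time series

`mhvg` turns an M-channel time series into an M-layer network and reads the
dynamics off its structure. Each channel is mapped to its **horizontal
visibility graph** (HVG): time points `i < j` are linked iff every
intermediate value is strictly below the smaller endpoint,
`x(k) < min(x(i), x(j))`. Stacking the M per-channel HVGs over the shared
time-point node set gives a **multiplex visibility graph**, and two scalars
summarise how much structure the channels share:

- **Average edge overlap**

  ω = Σ_{i<j} Σ_α a_ij^[α] / ( M · Σ_{i<j} 1{Σ_α a_ij^[α] > 0} ),

  the mean fraction of layers carrying an edge of the union edge set;
  ω ∈ [1/M, 1], with ω = 1 only for identical layers. `M·ω` is the expected
  number of layers per edge — a microscopic coherence meter.

- **Interlayer degree mutual information**

  I_αβ = Σ P(k^[α], k^[β]) log [ P(k^[α], k^[β]) / (P(k^[α]) P(k^[β])) ],

  the mutual information between the degree sequences of two layers,
  estimated from the node-wise joint degree counts. Averaging over layer
  pairs gives a scalar order parameter `I`; the full matrix {I_αβ} is the
  weighted **graph of layers**, a functional network built without the
  symbolization step (and its partition ambiguities) that plagues standard
  approaches. Backbone and maximum-spanning-tree summaries, plus windowed
  (temporal multiplex) profiles, come along.

The package ships its validation substrate: a **coupled map lattice**
simulator, `x_{t+1}^[α] = (1−ε)f(x_t^[α]) + (ε/2)[f(x_t^[α−1]) +
f(x_t^[α+1])]` with `f(x) = 4x(1−x)`, on a ring or chain, plus a globally
coupled mean-field variant — a workhorse model whose dynamical phases
(fully developed turbulence, pattern selection, intermittency,
synchronisation) are well charted, so the metrics can be checked against
known transitions. A fixed-partition symbolic mutual-information baseline
is included for comparison.

Intended users: anyone inferring functional structure from multichannel
recordings — physiological signals, neural data, asset prices, coupled
dynamical systems.

## Worked example

```r
library(mhvg)

# five diffusively coupled chaotic logistic maps in the pattern-selection
# phase (eps = 0.17) vs fully developed turbulence (eps = 0.05)
for (eps in c(0.05, 0.17)) {
  x <- simulate_cml(cml_params(M = 5, epsilon = eps, N = 16384, seed = 1))
  mux <- build_multiplex(x)
  cat(sprintf("eps = %.2f   omega = %.3f   I = %.3f\n", eps,
              average_edge_overlap(mux), mean_interlayer_mi(mux)))
}
#> eps = 0.05   omega = 0.451   I = 0.023
#> eps = 0.17   omega = 0.486   I = 0.818
```

Both metrics jump when chaos is suppressed in favour of a selected
periodic pattern: layers share far more microscopic edge structure
(`omega`) and their degree sequences become strongly dependent (`I`, in
nats). At weak coupling the graph of layers instead reveals the wiring of
the underlying system — the five largest I_αβ weights sit exactly on the
ring-adjacent map pairs:

```r
x <- simulate_cml(cml_params(M = 5, epsilon = 0.05, N = 16384, seed = 7))
gl <- graph_of_layers(build_multiplex(x))
maximum_spanning_tree(gl)$edges   # follows the ring
```

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/mhvg.R simulate-cml --M 5 --eps 0.17 --N 16384 --seed 1 --out series.csv
Rscript inst/cli/mhvg.R multiplex --in series.csv
Rscript inst/cli/mhvg.R windows --in series.csv --window-length 4096
```

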