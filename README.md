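# qubofs

Mutual-information QUBO feature selection for small images.

## The problem

Picking the *k* most useful pixels out of *n* (for compressed
acquisition, dose reduction, or interpretable models) is a combinatorial
`choose(n, k)` search. A standard information-theoretic formulation
casts it as a **quadratic unconstrained binary optimization** (QUBO)
over selection masks `x ∈ {0,1}^n`:

    min  xᵀQx   with   Q_ii = −I(x_i, y)   (importance: MI with the label)
                       Q_ij =  R(x_i, x_j) (redundancy: MI between pixels)

so selecting informative pixels lowers the energy while selecting
mutually redundant ones raises it. MI is estimated from empirical
contingency tables after per-feature quantile binning (20 bins). The
k-of-n constraint is enforced either with the quadratic penalty
`α(Σx − k)²` or — because that penalty makes the problem graph fully
connected, which annealing hardware cannot embed — with a
sparsity-preserving **linear Ising penalty**: a uniform diagonal offset
`α_l`, tuned until the solution has exactly k ones.

This package implements the whole pipeline for 28×28-style grayscale
image datasets (MedMNIST-format NPZ archives or a planted-structure
synthetic generator), including the hardware-motivated reductions
(2×2 max-importance block subsampling: 784 → 196 variables; top-2000
coupling thresholding), classical solvers standing in for the annealer
(exhaustive enumeration for n ≤ 22, multi-restart simulated annealing
above), baseline selectors (random, grid-sampled, Lasso), and a
convolutional decoder that scores any mask by test-set reconstruction
MSE. It is aimed at researchers studying QUBO/Ising formulations of
feature selection who need a reproducible, fully classical desk-scale
harness.

## Worked example

Plant 6 informative pixels and 2 redundancy groups in 8×8 images, then
recover a 4-pixel mask through the sparsified pipeline:

```r
library(qubofs)
spec <- synthetic_spec(n_samples = 1000, height = 8, width = 8, n_classes = 4,
                       informative_pixels = 6, redundancy_groups = 2,
                       group_size = 3, seed = 7)
train <- generate_synthetic(spec)
fd  <- flatten(train)                      # 64 features, row-major coord map
dd  <- discretize(fd, n_bins = 20)         # quantile bins
imp <- estimate_importance(dd)             # I(x_i, y) in nats
sm  <- subsample_by_importance(imp, fd$shape, block = c(2, 2))  # 64 -> 16
ddr <- estimate_redundancy(qubofs:::restrict_discretized(dd, sm$kept_indices))
mi  <- structure(list(importance = imp[sm$kept_indices], redundancy = ddr,
                      n = 16L), class = "mi_matrices")
q   <- threshold_couplings(build_mi_qubo(mi), m = 30)
tuned <- tune_linear_penalty(q, k = 4, solver = "sa",
                             p = anneal_params(n_reads = 200, sweeps = 50,
                                               seed = 11))
tuned$result
select_features(tuned$result, fd$shape, sm)
```

Output:

```
<solve_result [sa]: energy=-0.665969, weight=4/16>
     row col
[1,]   2   6
[2,]   3   5
[3,]   7   6
[4,]   7   8
```

The mask has exactly k = 4 ones (`weight=4/16`; the tuner found
`α_l ≈ 0.036` without needing repair) and its energy is the tuned-QUBO
objective of the returned mask. Two of the four selected pixels, (2,6)
and (3,5), are planted informative pixels; the energy trades the
remaining importance against the redundancy among the planted pixels,
which is exactly the behaviour the redundancy term is there to enforce.
The same stages run end to end via `run_sparsified_experiment()`, which
also trains the reconstruction decoder and reports mean ± sd test MSE
over repeats, and via the CLI (`inst/cli/qubofs`): `simulate-data`,
`build-qubo`, `sparsify`, `solve`, `train-decoder`, `benchmark`.

## Layout

- `R/`, `src/` — implementation (MI estimation and SA kernels in C++)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/qubo-feature-selection.Rmd` — model, parameter and design
  documentation
- `scripts/acceptance.R` — the acceptance report above
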