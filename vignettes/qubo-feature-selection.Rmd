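---
title: "Mutual-information QUBO feature selection: model, reductions, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information QUBO feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qubofs)
```

## The selection model

Given a dataset of $N$ square grayscale images $\mathbf{X}^i \in [0,1]^{W
\times W}$ with class labels $y^i$, each pixel is treated as one feature
of the row-major flattened vector $\mathbf{x}^i \in \mathbb{R}^n$,
$n = W^2$. Choosing $k$ of $n$ pixels is cast as a quadratic
unconstrained binary optimization (QUBO) over masks
$\hat{\mathbf{x}} \in \{0,1\}^n$:

$$
\min_{\hat{\mathbf{x}}} \; \hat{\mathbf{x}}^\top Q\, \hat{\mathbf{x}}
 = \sum_i Q_{ii}\hat{x}_i + \sum_{i<j} Q_{ij}\hat{x}_i\hat{x}_j ,
$$

with $Q_{ii} = -I(x_i, y)$ (*importance*: mutual information of a pixel
with the label, so informative pixels lower the energy when selected)
and $Q_{ij} = R(x_i, x_j)$ (*redundancy*: MI between two pixels, so
co-selecting mutually informative pixels raises it). Both quantities are
plug-in estimates from empirical contingency tables after per-feature
quantile discretization into at most `n_bins = 20` bins; labels are
discrete and are not binned.

Assumptions worth stating:

* The plug-in MI estimator is biased upward by roughly
  $(B_1-1)(B_2-1)/2N$ nats for a $B_1 \times B_2$ table; no bias
  correction is applied (none is applied in the reference protocol).
  With $N = 2000$ and $20 \times 20$ tables the pairwise bias is about
  0.1 nats, a uniform offset on all couplings that the thresholding and
  penalty stages inherit.
* MI is reported in nats. The log base is a uniform scale on $Q$ and
  cannot change the argmin; it is fixed here once.
* $0 \cdot \log(0/q) = 0$; estimates are clamped at zero (round-off
  only — clamping beyond $10^{-9}$ raises an internal error).
* Quantile ties: duplicate cut points are merged and cut points at or
  below the minimum are dropped, so discrete-valued pixels produce fewer
  effective bins instead of empty ones; a constant feature has exactly
  one bin and zero MI with everything.

## Cardinality constraints

The $k$-of-$n$ constraint can be enforced two ways:

* **Quadratic penalty** $\alpha(\sum_i \hat{x}_i - k)^2$, implemented by
  its algebraic expansion: $\alpha(1-2k)$ on every diagonal entry,
  $2\alpha$ on every unordered pair, $\alpha k^2$ on the offset. It is
  zero exactly at Hamming weight $k$ and strictly convex in the weight,
  but makes the problem graph fully connected. The package default
  $\alpha = n \cdot \max_{ij}|Q_{ij}|$ is a package choice (the
  reference protocol does not state its value); it is large enough that
  any violation costs more than the whole MI range, so exact solvers
  always return weight $k$.
* **Linear Ising penalty**: a uniform diagonal offset $\alpha_l$ that
  leaves the coupling graph untouched. The optimum's Hamming weight is
  non-increasing in $\alpha_l$ (each flip's marginal cost rises
  uniformly), so $\alpha_l$ is tuned by deterministic search —
  geometric bracketing from step $\max_i |Q_{ii}|/10$, then bisection —
  until the solver returns exactly $k$ ones. On plateaus or degenerate
  landscapes where no $\alpha_l$ attains exact $k$, the closest mask is
  greedily repaired (add the unselected variable with the lowest
  marginal energy increase, or remove the selected one freeing the
  most, repeatedly) and the result is flagged `repaired`. The repair
  fallback is a package addition; the tuner re-solves per candidate
  $\alpha_l$, which is the cleaner semantics when the reference leaves
  the point open.

The Ising form is an exact affine change of variables; both the
$\{-1,+1\}$ spin convention (annealer-API default) and the
$\{-\tfrac12,+\tfrac12\}$ convention are supported, with offsets tracked
exactly so energies are comparable across constraint variants.

## Hardware-motivated reductions

Annealing hardware restricts both variable count and connectivity, so
the pipeline mirrors the hardware-shaped reductions:

1. **Block subsampling**: partition the grid into non-overlapping
   $2\times2$ blocks and keep each block's highest-importance pixel
   ($784 \to 196$ for $28 \times 28$ images). Ties go to the smallest
   row-major index, making the map deterministic.
2. **Coupling thresholding**: keep the 2000 largest-magnitude couplings
   of the reduced problem; ties at the cutoff break lexicographically.
   After thresholding no discarded coupling exceeds any kept one.
3. **Linear penalty** instead of the quadratic one, so the sparsity
   just created is not destroyed. Because the penalty is purely
   diagonal, thresholding before or after adding it is equivalent; the
   package thresholds first so the cardinality mechanism can never be
   thresholded away.

Redundancy for the reduced problem is computed on the kept columns only
(19 110 pairs instead of 306 936) — numerically identical to slicing a
full matrix, since binning is per-feature.

## Solvers

The annealer (and the tabu-decomposition heuristic used classically at
full scale) is treated as a black box returning the lowest-energy
sample. Two classical stand-ins are provided:

* `solve_exhaustive()`: Gray-code enumeration up to $n = 22$,
  lexicographic tie-break — the ground-truth oracle.
* `solve_sa()`: multi-restart single-spin-flip Metropolis with
  geometric cooling (default 1000 reads, mirroring the hardware read
  count, 100 sweeps each). Temperatures auto-scale from the instance's
  maximum single-flip magnitude ($T_{hot} = \max_i(|Q_{ii}| +
  \sum_j|Q_{ij}|)$, $T_{cold} = 10^{-4} T_{hot}$) — a package choice,
  since no classical schedule is prescribed. The solver owns its RNG
  stream (xorshift, seeded per read), so results are pure functions of
  (problem, parameters, seed) and R's global RNG is never touched. A
  proposal whose acceptance probability is below $10^{-12}$ is rejected
  without consuming randomness; this is deterministic and changes
  nothing statistically meaningful.

On random instances with $n \le 14$, SA with default-scale parameters
attains the exhaustive optimum in well over 95% of cases (this is an
acceptance criterion, recomputed by the test suite on a fixed seed
bank).

## The synthetic stated world

`synthetic_spec()` defaults describe the world all desk-scale claims
are tested in: $N = 2000$ samples of $28 \times 28$ images, 8 uniform
classes, and three pixel populations:

* **25 informative pixels**: intensity mean $0.5 \pm 0.25$ depending on
  the class through a seeded random $\pm 1$ sign table per (pixel,
  class), plus $\mathcal{N}(0, 0.15^2)$ noise, clipped to $[0,1]$.
  Random class profiles keep informative–informative correlation low
  (as for spatially separated discriminative structures), so importance
  ($\approx 0.5$–$0.7$ nats at these settings) dominates their mutual
  redundancy.
* **5 redundancy groups of 4 pixels**: each group shares one
  $\mathrm{Unif}(0.2, 0.8)$ latent per sample plus
  $\mathcal{N}(0, 0.05^2)$ member noise — within-group pairwise MI is
  large, so the QUBO avoids co-selecting group members.
* **background noise**: $\mathcal{N}(0.5, 0.15^2)$, clipped.

These effect sizes were chosen once, from the MI arithmetic above
(signal $\gg$ estimation bias at $N \ge 1000$, `n_bins = 20`), before
the acceptance runs. What a green test establishes: the estimator ranks
planted pixels above noise, the pipeline returns exact-$k$ masks, and
masks selected by the MI QUBO reconstruct better than random masks in
this world. What it does not establish: performance on real image
distributions, where pixels are spatially correlated, classes are
imbalanced, and images may be misregistered — none of which the
generator models (registration jitter was considered and left out).

## Reconstruction evaluation

A mask is scored by training a decoder that maps the $k$ selected pixel
values back to the full image: linear layer to $c_1 \times (W/4)^2$,
ReLU, two transposed convolutions (kernel 4, stride 2, padding 1;
$W/4 \to W/2 \to W$) with ReLU then sigmoid, trained with Adam
(lr 0.001) for 20 epochs on MSE. Channel counts, kernel geometry and
batch size (128) are package choices where the reference is silent;
defaults are $c_1 = 32$, $c_2 = 16$, and the acceptance tests use a
smaller $16/8$ decoder to stay inside the desk-scale budget. Sides not
divisible by 4 are rejected rather than silently padded. The reported
error is the pooled mean squared error over all pixels of all test
images (identical to image-then-pixel averaging at fixed image size).
Training is seeded end to end; two runs with the same data, mask and
seed produce identical loss histories to within 1e-6.

The network and its gradients are implemented directly on BLAS matrix
operations (each transposed convolution is a sum over the 16 kernel
offsets of gather–matmul–scatter steps); gradients are verified against
finite differences in the test suite. No deep-learning backend is
required.

Comparators: `random` (uniform $k$-subsets), `sampled` (a
$g \times g$ lattice at `round(linspace(0, W-1, g))` per axis, excess
dropped in raster order — the placement formula is fully specified here
because the reference gives none), `lasso` (one-vs-rest L1 logistic
fits; the largest path penalty with $\ge k$ active features, ranked by
maximum absolute coefficient), and two transformed-feature adapters
(`autoencoder`: a jointly trained linear encoder feeding the same
decoder; `spca`: rank-$k$ PCA with hard-thresholded, renormalized
loadings, a documented stand-in since no sparse-PCA implementation is
available here). The transformed-feature methods compress rather than
select; they are evaluated through the same decoder machinery and never
asserted on quantitatively.

## Numerical choices and degenerate inputs

* Coefficient storage is upper-triangular ($i < j$); symmetric input is
  folded by summation, exact zeros are dropped.
* Tie-breaking is lexicographic everywhere (solver masks, threshold
  cutoffs, block argmax), so every path is reproducible.
* Seeds: every stage derives child seeds from one master seed via a
  fixed integer mix (`derive_seed`), all below $2^{31}$.
* Degenerate cases: constant features (one bin, zero MI), flat QUBOs
  (tie rule returns the empty mask; penalty tuning falls back to
  flagged greedy repair), zero-sweep SA (returns the seeded random
  initial mask).

## Known limitations

* Solving the *dense* 784-variable QUBO with single-spin-flip SA under
  a large quadratic penalty is ineffective (every weight-$k$ mask is a
  local minimum); the full-QUBO route is exercised with the exhaustive
  solver at small $n$. At full scale a decomposition or tabu solver
  should be plugged in through the solver interface.
* The estimated redundancy of independent pixel pairs is dominated by
  the $\approx (n_{bins}-1)^2/2N$ plug-in bias; thresholding therefore
  also ranks estimation noise. This matches the reference protocol
  (which applies no correction) but means kept couplings at desk-scale
  sample sizes are noisy.
* Minor embedding, chain strength, anneal schedules and other
  hardware-side concerns are out of scope; the SA solver stands in for
  the annealer as a sample source only.
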