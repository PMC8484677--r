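---
title: "Methods: kernel-based dynamic and higher-order correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-based dynamic and higher-order correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hocorr)
```

This vignette documents the estimators, the simulators, and the design
decisions behind them: what is being computed, which knobs matter, and
where the genuinely open choices were resolved.

## The instantaneous correlation estimator

Given a `T × K` timeseries **X**, the static Pearson correlation
between two columns sums products of deviations about the column
means. The dynamic estimator replaces the column mean with a
*kernel-weighted* mean centred on the timepoint of interest,

$$\tilde{x}_t(k) = \sum_{\tau=1}^{T} \kappa_t(\tau)\, X(\tau, k),$$

and `dynamic_corr()` offers two variants of the remaining sums:

* **`as_printed`** (default): the cross-product and squared-deviation
  sums run *unweighted* over all timepoints; only the centring is
  local. The kernel therefore acts through the reference point about
  which deviations are measured. This form is well defined for an
  exact Dirac delta kernel (the weighted variance of a one-point
  window never arises) and is the variant used in all recovery
  benchmarks in this package.
* **`fully_weighted`**: the kernel also weights the cross-product and
  variance sums — the conventional weighted Pearson estimator. It is
  sharply local but undefined for the exact delta (0/0) and can
  produce negative "variances" under the signed Mexican-hat weights;
  both conditions raise errors rather than returning NaN.

Both variants reduce *exactly* to the static Pearson correlation under
the uniform kernel, and both are bounded in [−1, 1] for non-negative
weights by Cauchy–Schwarz. Neither variant is canonical in the
field's usage, and estimates from the two are not generally
comparable; the package keeps both behind `mode` and defaults to the
locally-centred form, which remains defined for every kernel in the
bank. The two differ most for narrow kernels, so conclusions about
narrow-kernel behaviour should state the mode (the shipped benchmarks
use `as_printed` throughout).

Numerical notes. Columns are centred before the algebraically expanded
sums are evaluated; this is mathematically a no-op (the estimator is
invariant to shifting or positively rescaling any column) but prevents
catastrophic cancellation for columns with large offsets. Any
effective variance below `1e-12` is an error naming the timepoint and
feature — constant columns cannot be correlated. Timepoints are
1-based everywhere.

## Kernels

`kernel_spec()` supports `uniform`, `dirac_delta` (an exact one-hot
vector, not a narrow Gaussian), `gaussian`, `laplace`, and
`mexican_hat`. The scalar width maps to the parameter conventionally
drawn for each family: the Gaussian's variance σ² (samples²), the
Laplace's scale *b* (samples), the Ricker wavelet's σ (samples).

Weights are evaluated on the observed range `1..T`, truncated, and
renormalized per centre timepoint, so edge timepoints receive
renormalized one-sided windows. Non-negative families renormalize to
`sum(w) = 1`, which is what makes the weighted centring a genuine
mean. The Mexican hat cannot be normalized that way: its raw discrete
sum at interior timepoints is ~0 by construction (the wavelet
integrates to zero, and the discrete interior sum is zero to machine
precision for widths ≳ 2), so dividing by it would amplify the weights
without bound. It is instead normalized by the sum of *absolute*
weights (`sum(|w|) = 1`). Its "mean" is then a local-versus-surround
contrast — which is exactly the role of a centre–surround wavelet —
and the `as_printed` estimator remains bounded for it. This is the one
place the package departs from treating every kernel identically; the
departure is forced by the arithmetic, and it is what keeps the
default analysis bank ({gaussian, laplace, mexican_hat} × widths
{5, 10, 20, 50}) usable at every timepoint.

## DISFC

`disfc()` computes, for each participant, the dynamic
cross-correlation between that participant's features and the
leave-one-out average of the others (`loo_average()`), Fisher-z
transforms it, averages the symmetrized z-matrices across
participants, and maps back. Correlations are clipped to
±(1 − 10⁻¹⁰) before `atanh` so exact ±1 stays finite; the identical
clip is applied everywhere the transform is used. The inverse
transform is the standard `tanh` (a typeset form of it sometimes seen,
with the shift inside the exponent, algebraically reduces to a
constant and cannot be an inverse). Diagonal entries of the
per-participant
cross-correlation matrices are genuinely below 1 (self vs.
others-average) and are deliberately passed through without
re-unitization — no step in the averaging formula re-imposes a unit
diagonal, and re-imposing one would discard the attenuation
information.

## Projections and the higher-order recursion

A correlation stream **Y**ₙ is projected to `T × K` features **X**ₙ
either by PCA or by per-timepoint eigenvector centrality.

*PCA* (`pca_fit()`/`pca_apply()`) is fitted once on the row-stacked
streams of all participants in an analysis, so training and test
groups share one space. Columns are centred, not scaled (the entries
are already on the correlation scale); component signs are fixed by
making each component's largest-magnitude loading positive. When the
centred stream has lower rank than `K` (a constant-correlation stream
has rank 0), the remaining components are taken from the SVD's
orthonormal null-space basis: their scores are ≈ 0, the loadings stay
orthonormal, and degenerate streams project cleanly instead of
erroring — necessary because constant correlation structure is a
legitimate (and simulated) input.

*Eigenvector centrality* (`centrality_project()`) needs non-negative
edge weights; correlations are signed. The default takes absolute
values (Perron–Frobenius then guarantees a non-negative principal
eigenvector); a `(1 + r)/2` shift is available behind the `weights`
argument since the "right" mapping is not derivable from first
principles. Exactly tied dominant eigenvalues (e.g. the identity
matrix, or two disconnected equal blocks) are resolved
deterministically by projecting the all-ones vector onto the tied
eigenspace — the identity matrix therefore yields the uniform vector
`1/√K`.

`hocorr()` alternates estimation and projection. With
`decode_mode = TRUE`, all orders below the top are estimated with the
exact delta kernel and only the final step uses the analysis kernel:
repeated wide-kernel estimation compounds temporal blur, which would
bias timepoint-resolved analyses against higher orders. Intermediate
PCA spaces in a decoding run are fitted on those delta-kernel streams
across all participants and reused for every group. Order 0 passes
through untouched. The stack for orders 0..n stores `(n+1)·T·K`
values; `stack_storage()` audits this.

## Synthetic data

`simulate_first_order()` draws `T` independent observations
`s_t ~ N(0, Σ_t)` with Σ_t following one of four regimes: *constant*
(one covariance), *random* (a fresh covariance each timepoint),
*ramping* (linear interpolation between two anchors, with the
interpolation denominator generalized to `T − 1`), and *event*
(`n_events` covariances in equal consecutive blocks; `T` must divide
evenly). Covariances are Wishart-type Gram matrices `CCᵀ` with
standard-normal `C`; the stored ground truth is the correlation
normalization `D^{-1/2} Σ_t D^{-1/2}`, since recovery is scored
against correlations, not covariances. Defaults are K = 50, T = 300
for first-order benchmarks and K = 10 for higher-order ones — the
order-2 generator needs `O(K⁴)` memory, and the smaller base dimension
keeps the two benchmarks' recovery scores on comparable feature
counts.

`simulate_higher_order()` lifts the order-1 correlation template to
order *n* via Kronecker self-products `m_{j+1} = m_j ⊗ m_j`
(independently at each timepoint), then samples backwards: a draw from
`N(0, m_j)` is reshaped row-major to a square matrix, symmetrized by
reflecting its upper triangle over the diagonal, and repaired to a
valid correlation matrix before serving as the realized order-`j−1`
covariance; the final K-vector draw is the observation. Two choices
here are genuinely open and resolved as follows:

* *PSD repair.* The reshaped, symmetrized draw is not positive
  semidefinite in general. Eigenvalues are clipped at `1e-10` and the
  diagonal is re-unitized. Clipping is not neutral: for a symmetric
  zero-mean draw it biases the repaired matrix toward the template
  that generated it (the positive part of an orthogonally invariant
  fluctuation has expectation proportional to the identity in the
  template's eigenbasis). This bias is what makes the realized
  intermediate matrices resemble noisy versions of their templates,
  and recovery numbers would shift under a different repair rule.
* *What "truth" means per order.* The stored truth is the noiseless
  template at every order; the realized (noisy) intermediate matrices
  are kept separately in `$realized`. Generation noise therefore
  enters between the top-order template and the data — it propagates
  from high orders down, so lower-order structure in the data is
  noisier relative to its template than top-order structure is.

`simulate_group()` shares one covariance timecourse (and, at higher
orders, one realized backward chain) across `P` participants and mixes
a shared signal draw with participant-specific noise,
`s^p_t = √(1−a)·z_t + √a·ε^p_t`, both components `N(0, Σ_t)`, so every
participant's marginal distribution is exactly `N(0, Σ_t)` for any
mixing weight. The default `a = 1` gives fully independent draws —
participants share only the correlation structure, which is the
inter-subject functional connectivity premise. Decoding demonstrations
use `a = 0.5` ("strong shared structure": equal parts shared signal
and idiosyncratic noise); with `a = 1` the across-group decodability
of zero-mean Gaussian data is weak, because cross-participant
correlations of independent draws have zero expectation at every
timepoint regardless of Σ_t.

What the generators do *not* emulate: temporal autocorrelation of the
noise, non-Gaussian marginals, hemodynamic filtering, and
participant-specific correlation structure. Passing benchmarks on
these data shows the estimators recover what they are defined to
recover; it does not certify performance on real neural recordings.

## Recovery scoring

`recovery_timecourse()` correlates, at each timepoint, the vectorized
estimated correlation matrix with the vectorized reference. Two
conventions matter:

* *The diagonal is excluded* (strict upper triangle). Estimated and
  true matrices both carry an exact unit diagonal; including those
  entries adds a constant matched component to both vectors and
  inflates every score — enough, at K = 50, to invert the ordering of
  narrow versus wide kernels on unstructured data. `include_diagonal =
  TRUE` restores the inflated variant for comparison.
* *Higher orders are scored without dimensionality reduction.* A
  K-column projection of the order-1 stream would make the order-2
  estimate incommensurable with the `K² × K²` Kronecker template. The
  order-2 estimate therefore uses the estimated off-diagonal
  correlation entries themselves — the `(K²−K)/2` distinct pairs — as
  intermediate features (the unit-diagonal entries are constant and
  carry no signal), with the same analysis kernel at every step, and
  is scored against the matching submatrix of the template,
  `m_2[(a,b),(c,d)] = m_1(a,c)\,m_1(b,d)`.

`summarize_recovery()` reports per-timepoint means with t-interval 95%
confidence bands across replicate datasets (the interval method is a
choice; nothing in the underlying procedure prescribes one).
Edge-of-series dips and event-boundary ramps are finite-sample
effects and are reported, not corrected.

One benchmark claim did not survive implementation and is worth
stating plainly: on order-2 data whose templates are redrawn
independently at *every* timepoint (the random regime), both
first-order and second-order recovery are statistically
indistinguishable from zero under every estimator variant and scoring
convention we examined — a windowed estimator simply has no
information about a per-timepoint fresh template beyond a single
timepoint's worth of data. The corresponding acceptance expectation
(second-order recovery exceeding first-order there) is left failing
rather than engineered around; the three temporally structured regimes
reproduce their expected ordering (first-order recovery above
second-order) robustly.

## Temporal decoding

`run_decoding()` repeats, for each of `folds` (default 10) random
group assignments and each kernel in the bank: order-0 features are
each group's mean timeseries (a choice — the group pattern for raw
activity is not uniquely prescribed; the mean mirrors the
leave-one-out averaging spirit of DISFC), order-n features are the
group's DISFC over members' order-(n−1) delta-kernel stacks with the
analysis kernel. Per-order weights are optimized on a nested split of
the training group and evaluated once on the held-out test group.

Decoding accuracy is piecewise constant in the weights, so gradient
ascent cannot act on it directly. `optimize_weights()` ascends a
differentiable surrogate — the softmax probability mass on the correct
timepoint, temperature 0.1 (in correlation units: sharp enough to
approximate the argmax, smooth enough to carry gradients) — by BFGS on
softmax-reparameterized weights from multiple starts (uniform and each
vertex), then returns the candidate with the best *true* accuracy.
Because the uniform weights and every vertex are always candidates,
the returned accuracy never falls below theirs. Argmax ties in the
classifier break to the lowest template index; fold splits differ by
at most one participant between groups.

`compare_feature_sets()` runs *paired* two-tailed t-tests across folds
on kernel-averaged accuracies (paired because fold assignments are
shared across feature sets), each set against each other and against
the mean of the rest, with the mean optimized weight per order on the
summary matrix's diagonal. A constant non-zero fold-wise difference is
reported as an infinite t with p = 0 rather than an error. Chance
levels are calibrated by permutation (`chance_accuracy_band()`).

## Problem sizes used in the shipped checks

The test suite and acceptance script run the benchmarks at 20
replicates per regime (10 for the duration sweep) with K = 50, T = 300
first-order data, K = 10 order-2 data, and decoding at P = 8, T = 100,
K = 10 with 5 folds and a single delta kernel. These sizes give
margins that are stable across seeds for every reproduced ordering
while keeping the full suite in the minutes range; raising the
replicate counts or using the full 12-kernel bank sharpens the
estimates but does not change the orderings asserted here.

## Known limitations

* Estimation error compounds across orders: order-n features inherit
  every lower order's noise and the information lost to each
  projection. High-order estimates are meaningful relative to, not
  independent of, the low-order pipeline that produced them.
* `as_printed` mode localizes only through the centring term; its
  effective temporal resolution is coarser than the kernel width
  suggests, and narrow-kernel results differ materially between the
  two modes.
* The Kronecker construction ties higher-order templates rigidly to
  the order-1 template (`m_2 = m_1 ⊗ m_1`); it cannot express
  higher-order structure that contradicts lower-order structure.
* Graph measures other than eigenvector centrality, lagged
  cross-correlation, partial correlation, and state-dependent
  (e.g. semi-Markov) kernels are out of scope; the projection step
  exposes a plug-in surface for symmetric-matrix-to-vector measures.
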