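---
title: "Multi-scale frequency-band ensembles: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale frequency-band ensembles: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfbel)
```

## The model

The package classifies samples whose features carry a channels × bands
structure — typically per-channel differential-entropy (DE) features from a
handful of EEG frequency bands. The working hypothesis is that the *width* of
the band grouping matters: single bands, small groups of adjacent bands, and
the full concatenation each expose different structure, and which view is
best varies across subjects and sessions. Rather than committing to one
width, the ensemble runs all of them and learns how much to trust each.

With `s` bands there are `s` scales; scale `j` slides a window of `j`
adjacent bands across the spectrum, giving `p_j = s − j + 1` patches. Only
adjacent bands are grouped — the band axis is ordered (slow to fast
oscillations), so contiguous windows are the meaningful groupings and the
combinatorial explosion of arbitrary subsets is avoided.

Three layers sit on top of the patch decomposition:

* **Collaborative representation (CRC)** classifies one patch. The test
  patch is coded over the matrix of *all* training patches with an ℓ2
  penalty, `α* = (XᵀX + λI)⁻¹Xᵀy`, and the class whose columns reconstruct
  it best wins. CRC assumes class-conditional samples lie near
  low-dimensional subspaces that differ between classes; the collaborative
  (all-classes) coding makes the per-class residuals comparable.
* **Majority voting** fuses the `p_j` patch labels of a scale into the scale
  label `r_j`. Within a scale all patches are treated equally; there is
  deliberately no intra-scale weighting.
* **Ensemble-weight learning** fuses the scale labels. On a validation split
  the matrix `D` records per-scale correctness as ±1; weights on the
  probability simplex minimize `‖1_m − Dw‖²`, which pushes every validation
  sample's weighted margin `Σ_j w_j d_pj` toward the ideal value 1. Because
  the simplex contains every one-hot vector, the optimum can never be worse
  (on validation) than the best single scale — the fusion is safe by
  construction. Note the objective is the squared-norm form; its linear
  expansion differs by a constant and by squaring, but the squared form is
  what the alternating solver optimizes.

## Parameters that matter

* `lambda` (CRC ridge penalty, default `1e-3`). Controls the
  bias–variance trade-off of the coding; the conventional tuning grid is
  `10^(-5:-1)` and `tune_lambda()` implements the grid search by global-scale
  validation accuracy. Results are typically flat across the grid on
  well-separated data.
* `normalize_columns` (default on). Unit-ℓ2 dictionary columns are standard
  CRC practice so every training patch contributes on the same scale;
  exposed as a flag because the un-normalized variant is occasionally
  wanted for calibrated magnitudes.
* `normalize_residual` (default on). Dividing the class residual by
  `‖α_k‖₂` rewards classes that explain the patch with substantial
  coefficients; it measurably sharpens discrimination and is the
  configuration under which the method is usually reported.
* `split` (default 0.5, stratified by class). The fraction of training data
  used to build dictionaries, with the rest forming the decision matrix.
  Each part must retain every class. When trial identifiers exist, whole
  trials are assigned to one side so that temporally correlated samples
  never straddle the split.
* Solver (`solver_config()`): multiplier initialized at all-ones, growth
  `rho = 1.1`, initial penalty `mu0 = 1e-3`, tolerance `1e-8`, at most 5000
  iterations (each costs only `O(s^2)`, and ill-conditioned interior optima
  occasionally need a few thousand). The initialization follows the standard
  choice for this augmented-Lagrangian scheme; see the numerical notes for
  `mu_max`.

## The solver in detail

The QP `min_{w≥0, Σw=1} ‖1 − Dw‖²` is solved by variable splitting: an
auxiliary `v` decouples the quadratic, and the augmented Lagrangian
`vᵀMw − vᵀb + (μ/2)‖w − v + β/μ‖²` (with `M = DᵀD`, `b = 2Dᵀ1`) is
minimized alternately.

* The `v`-step is an unconstrained quadratic with closed form
  `v = w + (β + b − Mw)/μ` (its gradient at that point is exactly zero —
  property-tested).
* The `w`-step reduces to the Euclidean projection of
  `g = v − (β + Mᵀv)/μ` onto the simplex, computed via the shifted vector
  `h = g − mean(g) + 1/s` and the threshold root of `Σ(h_j − η)₊ = 1`. The
  root is found by Newton's method on this convex piecewise-linear function,
  starting at `η₀ = max(h) − 1` (where the function is nonnegative) with the
  one-sided slope `−#{j: h_j > η}` and a bisection fallback guarding against
  active-set cycling. The linear term `−vᵀb` is constant in `w` and
  correctly absent from this step.
* Multiplier and penalty then advance: `β ← β + μ(w − v)`, `μ ← ρμ`.

**Penalty ceiling.** Geometric penalty growth has a blind spot: once `μ` is
large both closed forms freeze (`v → w`, `g → v`), so the iterate stops
moving *wherever it happens to be* — the scheme behaves like projected
gradient descent with step `1/μ`, and a geometrically vanishing step sums to
a finite travel budget. On degenerate faces this can strand the iterate
measurably short of the optimum. The implementation therefore caps the
penalty at twice the largest diagonal entry of `M` (i.e. at the scale of the
problem's curvature), after which the multiplier updates behave like the
classical method of multipliers and finish the convergence. The penalty is
consequently non-decreasing rather than strictly increasing once the cap is
reached; `mu_max` is exposed in `solver_config()` for users who want the
uncapped schedule.

**Stopping rule.** Convergence is declared when `‖w − v‖∞` and the relative
change of `w` fall below `tol` *and* the iterate passes a projected-gradient
stationarity check (projecting one gradient step returns the point). Without
the third condition the freeze described above can masquerade as
convergence. On non-convergence the best iterate by objective value is
returned with a warning, never silently.

**Tie-breaking.** Majority voting, CRC's argmin and the final weighted vote
all break ties toward the lowest class index. Ties are genuinely possible
(even patch counts, duplicated dictionaries), and a deterministic,
order-independent rule keeps every prediction reproducible and
permutation-invariant. `λ = 0` is permitted but routed through a QR
least-squares solve and rejected for rank-deficient dictionaries rather than
inverting a singular Gram matrix.

## The synthetic generator

`synth_bands()` draws class-conditional Gaussian features: for band `f` the
`c` class means sit at the vertices of a regular simplex realized along
random orthonormal channel directions, with pairwise distance
`e_f · σ · √channels`, i.e. `e_f` is the per-channel standardized separation
(a Cohen's-d-like effect size). Two deliberate choices:

* The simplex is *uncentred* — class means are orthogonal directions, never
  antipodal pairs. Centring a two-class simplex puts the means at `±μ`,
  which a sign-invariant representation (ridge coding over normalized
  columns) cannot distinguish; real band-power features, which share a large
  positive offset, never look like that.
* Effect sizes are per-channel rather than whole-vector so that `e_f` has
  the same meaning regardless of the channel count, and `e_f = 0` erases all
  class information in band `f` exactly.

The generator emulates what the method needs — band-structured features
whose discriminability varies across bands, hence scales with different
single-scale accuracies — and nothing else. It does *not* simulate channel
covariance, temporal autocorrelation within trials, non-Gaussian artifacts,
or inter-subject variability. Tests passing on this generator show the
machinery (patching, coding, voting, weight learning) is correct and that
the ensemble recovers planted band structure; they do not certify accuracy
levels on real EEG.

## Design choices

* **Band-major flattening.** A sample's feature vector is the concatenation
  of per-band channel blocks (62 channels × 5 bands → 310 features with all
  Delta channels first). This is a convention, fixed and documented so that
  dictionaries and test patches always agree; `extract_patch` is pure column
  selection under it.
* **Dictionaries at test time.** After weight learning, the dictionaries
  presented to test data remain those of the fit part — the weights were
  calibrated against exactly those dictionaries. Refitting on the full
  training set is available (`refit = TRUE`) but off by default.
* **Validation samples are unweighted** in the decision matrix; every row of
  `D` counts equally.
* **Friedman/Nemenyi.** The omnibus rank test is delegated to
  `stats::friedman.test()`; only the critical-distance formula
  `CD = q_α √(k(k+1)/6N)` is implemented here, with `q_α` supplied by the
  caller from the standard table.

## Problem sizes and verification

The test suite verifies each layer against an independent route: ridge
coding against dense linear solves (200 random systems, dimensions ≤ 20×30),
classification against a from-scratch re-implementation (100 random 2–4-class
dictionaries), the Newton-root projection against the exact sort-based
construction (1000 random points, `s ≤ 8`), and the weight solver against
long-run projected gradient descent (50 random decision matrices, `m ≤ 50`,
`s ≤ 6`). The end-to-end recovery experiment uses 8 channels, 5 bands, 4
classes, one informative band at `e = 5`, 100 fit + 100 validation + 200
test samples per class; at these sizes the informative single-band patch
classifies essentially perfectly, uninformative patches stay at chance, and
the learned weights concentrate on the scales whose validation columns are
most accurate. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* CRC cost grows with the training-set size (an `n × n` factorization per
  patch dictionary); tens of thousands of training samples per patch would
  call for sub-dictionaries or approximate solvers not implemented here.
* The ensemble weights are only as good as the validation split; with very
  few validation samples per class the decision matrix is noisy and the
  learned weights can overfit it (the safe-by-construction guarantee holds
  on validation, not on test).
* Raw-EEG ingestion (EDF/BDF), DE feature extraction, artifact removal and
  cross-subject adaptation are out of scope; the package consumes
  precomputed band features.
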