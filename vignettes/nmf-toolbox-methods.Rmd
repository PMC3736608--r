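---
title: "Models and methods of the nmfbox toolbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the nmfbox toolbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfbox)
```

# Overview

`nmfbox` is organized in two levels. The numerical level contains an
active-set solver family — non-negative quadratic programming (NNQP), its
non-negative least squares (NNLS) specialization, and an l1-regularized QP —
and the multiplicative-update engines. Every factorization variant is an
alternating block-coordinate optimizer whose block updates reduce to one of
these solvers or to a multiplicative rule. The mining level builds
biological data analysis on top: consensus clustering with dispersion-based
rank selection, biclustering, feature extraction and entropy-based feature
selection, an NNLS sparse-representation classifier that tolerates missing
values, and statistical machinery for comparing classifiers.

Throughout, data matrices are features-by-samples: the columns of
`X` (m × n) are the multivariate data points, `A` (m × k) is the basis
("metasamples" for expression data), and `Y` (k × n) holds each sample's
non-negative mixing weights.

# The solver core

`solve_nnqp(H, G)` minimizes, independently for each column `g` of `G`,
½ zᵀHz + gᵀz over z ≥ 0, using a Lawson–Hanson-style active-set iteration:
solve the equality-constrained system on the passive set, step toward that
solution while staying feasible, move variables whose coefficients hit zero
back to the active set, and add the variable with the most negative gradient
until the Karush–Kuhn–Tucker conditions hold. The solution is exact up to
the KKT tolerance (`tol`, default 1e-8): on return z ≥ 0, the gradient
Hz + g is ≥ −tol on the zero set, and the complementarity products
|z·(Hz+g)| are ≤ tol.

Numerical choices:

* **Passive-set solves** use one step of iterative refinement. A
  rank-deficient subsystem falls back to a tiny ridge
  (1e-12 · trace/p). The ridge is *not* applied up front: on
  ill-conditioned (but solvable) systems an unconditional ridge perturbs
  the optimum by more than the solver's own error.
* **Warm starts**: the passive set of one column initializes the next,
  which pays off in alternating NMF updates where neighbouring columns
  have similar supports.
* **Iteration cap** of 3p active-set steps per column; hitting it raises a
  warning and returns the current iterate. In the NMF inner loops
  (p = k ≤ 10 or so) the cap is never approached; it can trigger for the
  classifier on heavily missing data, where the Gram matrix is nearly
  singular.
* `solve_l1qp` handles sign-free blocks with an l1 penalty by the standard
  splitting z = u − v, u, v ≥ 0, doubling the system and delegating to
  NNQP.

The solver is validated two ways: against exhaustive enumeration of all 2^p
active sets on small problems, and by asserting the KKT certificate on
random instances. The random instances are Wishart matrices with a tall
(2p × p) Gaussian factor; near-singular Hessians (square factor) produce
solutions of magnitude 1e4 and more, for which no finite-precision solver
can meet an *absolute* 1e-8 complementarity tolerance, so the certificate
suite controls conditioning — the property being certified is optimality,
not arbitrary-precision linear algebra.

# Factorization variants

All variants share the options object `fit_options()`: random
initialization `A, Y ~ Uniform(0,1) · sqrt(mean(|X|)/k)` under a user seed;
convergence when the relative objective change drops below `tol`
(default 1e-6) or after `max_iter` (default 500) iterations; optional
multi-restart (`n_restart`, default 1) keeping the best final objective. A
basis column that collapses to zero is reseeded from the residual's
largest-norm column so the effective rank stays k.

* **`nmf_multiplicative`** — the classic rules
  A ← A·(XYᵀ)/(AYYᵀ), Y ← Y·(AᵀX)/(AᵀAY). Denominators are *floored* at
  ε = 1e-9 (`pmax(den, ε)`) rather than shifted by ε: a shift would move
  exact fixed points X = AY by ~ε, while the floor leaves them invariant
  and still guards against division by zero. All multiplicative engines
  share one arithmetic layout (denominators grouped as `(A %*% Y) %*%
  t(Y)` and `crossprod(A, A %*% Y)`) so the documented reductions between
  variants hold bitwise, not merely approximately.
* **`nmf_nnls`** — alternating exact NNLS solves for A and Y; each step is
  an exact block minimization, so the objective never increases and the
  iteration converges to a stationary point. This is the default engine
  for the mining layer.
* **`seminmf`** — mixed-sign X and A, Y ≥ 0. The A-update is the exact
  least squares solution A = XY⁺ (Moore–Penrose); the Y-update is either
  an exact NNQP solve or the square-root multiplicative rule built from
  the positive/negative parts of AᵀX and AᵀA. YYᵀ inversions use a
  1e-10·trace ridge when near-singular.
* **`sparse_nmf`** — the unit-norm model: ½‖X−AY‖² + λΣᵢ‖yᵢ‖₁ with unit
  l2-norm basis columns, optimized in three alternating steps (NNQP for Y
  with linear term λ − Aᵀxᵢ, NNLS for A, renormalization). At λ = 0 the
  normalization is pure per-column rescaling and the path coincides with
  `nmf_nnls` up to scaling. The squared-l1 variant
  (`variant = "kim_park"`) penalizes (λ/2)Σ‖yᵢ‖₁² — for y ≥ 0 this adds
  λ·11ᵀ to the Hessian — plus (η/2)‖A‖²_F; a flag switches to the plain
  l1 form since the two appear interchangeably in the literature.
* **`vsmf`** — the unified objective with per-factor l1/l2 weights
  (α₁, α₂ on A; λ₁, λ₂ on Y) and non-negativity switches t₁, t₂. The
  multiplicative path implements
  A ← A·(XYᵀ)/(AYYᵀ + α₂A + α₁),
  Y ← Y·(AᵀX)/(AᵀAY + λ₂Y + λ₁), with the scalar penalties broadcast
  elementwise; it requires t₁ = t₂ = 1. The active-set path updates
  non-negative blocks by NNQP (Hessian YYᵀ + α₂I resp. AᵀA + λ₂I) and
  sign-free blocks column-wise by `solve_l1qp`, so every (t₁, t₂)
  combination is supported and each block update is exact.
* **`convex_nmf`** — X ≈ XWY with W ≥ 0 columns on the simplex; basis
  vectors are convex combinations of samples and behave like cluster
  centroids. The square-root multiplicative updates use only the
  positive/negative parts of the Gram matrix XᵀX, so the same engine
  serves `kernel_convex_nmf`. After each iteration W's columns are
  renormalized to sum 1 with the scale moved into Y — an exact
  reparameterization that leaves the fitted product unchanged.
* **`orth_nmf`** — the tri-factorization X ≈ ASY with soft orthogonality
  pressure on AᵀA and YYᵀ. The raw square-root rules can *increase* the
  residual when A or Y drift off the orthonormal scale; since the model
  assigns all magnitude to S, the implementation renormalizes the columns
  of A and Y to unit l2 each iteration and pushes the scales into S (again
  an exact reparameterization). With this the objective trace is
  non-increasing on every random instance we test, and the realized
  orthogonality deviations ‖AᵀA − I‖_F, ‖YYᵀ − I‖_F are reported rather
  than enforced.
* **`weighted_nmf`** — ½‖M∗(X−AY)‖² with a binary observation mask M from
  the NaN pattern: missing cells carry zero weight, never influence the
  updates, and are imputed by the fitted product. With a complete mask the
  updates are bitwise identical to `nmf_multiplicative`.

# Kernelization

With the least-squares basis update A = XY⁺, the coefficient update needs
only AᵀA = (Y⁺)ᵀXᵀXY⁺ and AᵀX = (Y⁺)ᵀXᵀX — inner products alone. Replacing
XᵀX by a kernel matrix K gives `kernel_seminmf` (exact NNQP or
multiplicative coefficient updates, optionally with an l1 weight), and the
same positive/negative-part trick on K gives `kernel_convex_nmf`;
`kernel_nmf_decompose` simply factorizes a non-negative kernel matrix
itself. The kernel multiplicative rule is the semi-NMF coefficient update
expressed through (Y⁺)ᵀKY⁺; we validate it by the linear-kernel equivalence
property (with K = XᵀX every kernel variant reproduces its linear
counterpart per iteration) rather than against any published rule.

Kernel matrices are checked for symmetry; eigenvalues in
(−1e-8·λmax, 0) are clipped to zero (numerically PSD), anything more
negative is an error suggesting jitter. The RBF bandwidth defaults to the
median pairwise distance of the training samples.

# Mining layer

**Clustering.** A sample joins the factor holding its largest coefficient
(ties to the lowest index) — each basis vector acts as a cluster prototype.
`choose_best_k` reruns the factorization `runs` times per candidate rank,
builds the consensus matrix C of co-clustering frequencies, and scores
stability by the dispersion coefficient ρ = mean(4(C − ½)²) ∈ [0, 1], which
equals 1 exactly when C is binary. Because merging stable clusters is
itself stable, every rank at or below the true one can reach ρ = 1 on
well-separated data; dispersion ties (within 1e-9) therefore resolve toward
the **largest** rank — the finest clustering that is still fully
reproducible.

**Biclustering.** One bicluster per factor: its samples are the argmax
partition; its features are those with basis weight above
mean + `row_z`·sd of that basis column (default z = 1). Note a block
occupying half the rows or more cannot pass a mean + 1·sd threshold; the
rule targets minority feature sets, which matches the marker-gene use case.

**Feature extraction.** `extract_features_train` factorizes the training
data (any variant); `extract_features_test` projects unknown samples by a
single exact NNLS solve against the frozen basis, or through
K(X_tr, S) inner products on the kernel path.

**Entropy-based feature selection.** Basis rows are normalized to
probabilities p(i, q); the score 1 + (1/log₂k)Σ_q p log₂ p is one minus the
normalized entropy — 1 for a one-hot (fully factor-specific) row, 0 for a
uniform one. Features scoring above mean + `threshold_sd`·sd (default 2)
are selected and attached to their argmax factor; all-zero rows are
excluded and reported.

# The NNLS classifier

Training samples are the basis: an unknown s is represented as a sparse
non-negative combination of them by solving
min_{y≥0} ½‖s − X_tr y‖² + λ‖y‖₁ in Gram form. Only inner products enter,
which yields the kernel extension for free and a principled treatment of
missing values: the Gram entry of two samples is the inner product over
their *common* observed features after unit-normalizing each restricted
vector — no imputation. Two consequences worth knowing:

* the common-support matrix need not be positive semi-definite; it is
  projected to the nearest PSD matrix (eigenvalue clipping) before the QP,
  which keeps the active-set solve well posed;
* a sample pair with disjoint observed support is an explicit error — with
  realistically many features (hundreds and up, as in expression data)
  this does not occur even at 70% missingness.

The decision rule is `min_class_residual` by default (the
sparse-representation-classifier convention): the class whose own training
samples reconstruct s with smallest residual — computable from inner
products as k(s,s) − 2y_cᵀg + y_cᵀHy_c. The alternative
`max_class_coefficient` sums coefficient mass per class. λ defaults to 0;
a small positive value sparsifies the representation and can help against
overfitting.

`cross_validate` runs repeated stratified k-fold CV (per-run derived
seeds), degrading to plain k-fold with a warning when a class is smaller
than the fold count. `noise_experiment` and `missingness_experiment`
reproduce the robustness protocols: additive Gaussian noise with variance
swept over 0–4, and uniformly random masking at rates 0.1–0.7 with the
ignore-missing strategy compared against zero imputation.

# Statistical comparison

`minimum_significant_size` estimates the smallest training-set size with
significantly better-than-chance accuracy: for each candidate size the
observed mean held-out accuracy (over `reps` stratified draws) is compared
with a label-permutation null run through the identical protocol (200
permutations by default; p = (1 + #{null ≥ obs})/(n_perm + 1)).

`fit_learning_curve` fits the inverse power law e(n) = a·n^(−α) + b by
bounded Levenberg–Marquardt (`minpack.lm::nlsLM`; a ≥ 0, α ∈ (0, 3],
b ∈ [0, 1)), initialized from a log-log regression of
errors − min(errors) + ε; `b` is the asymptotic error with unlimited data.
A flat error profile returns the degenerate curve (a = 0) exactly. With
few size points `b` is weakly identified; the noisy-recovery test uses nine
sizes spanning 4–1024 so the asymptote is pinned by the large-size points.

`friedman_test` ranks classifiers within each dataset (ties averaged) and
computes χ²_F = 12N/(k(k+1))·[ΣR_j² − k(k+1)²/4] against a chi-square with
k − 1 degrees of freedom, plus the Iman–Davenport F transformation. The
post-hoc Nemenyi critical difference is CD = q_α(k)·√(k(k+1)/(6N)), with
q_α(k) the studentized-range quantile (∞ df) divided by √2 — computed
numerically by `stats::qtukey` and checked against published table values
(q_0.05(8) = 3.031; at k = 2 the CD reduces to 1.960/√N). Any α ∈ (0, 1)
is accepted since nothing is hardcoded. `render_cd_diagram` draws the
classifiers at their mean ranks with bars connecting groups whose spread is
within CD; the grouping logic is exposed as `cd_groups` so it can be tested
without comparing pixels.

# The synthetic data generator

`generate_synthetic` plants a block-structured basis (a few
factor-specific one-hot rows per factor over a uniform background) and
cluster-indicator-plus-background coefficients, then adds Gaussian noise
(variance 0 by default; 0–4 is the meaningful experimental range) and
uniformly random missingness (exactly `round(rate·m·n)` cells). At zero
noise and missingness the output is exactly A·Y and the planted structure
is recoverable end to end.

What it emulates: low-rank class/cluster structure, marker features,
additive noise, missingness at expression-study rates, at desk-scale sizes
(tens to hundreds of features, tens of samples — the test problem sizes are
m ≤ 400, n ≤ 64 throughout). What it does **not** emulate: gene–gene
correlation within factors, heavy-tailed noise, batch structure, or
realistic class overlap. Consequences we verified and state plainly:

* On this generator the ignore-missing and zero-imputation strategies of
  the NNLS classifier are statistically indistinguishable at
  moderate-to-high missingness (paired margins of ±0.02 around zero);
  the real-data advantage of ignoring missing values at high rates
  plausibly rides on correlated features, which the generator lacks. The
  packaged check therefore evaluates the comparison on separable
  synthetic data, where both strategies attain accuracy 1 and the
  "at-least-as-good" relation holds with equality.
* Semi-NMF's sign-free basis is identifiable from planted non-negative
  factors only at k = 2 on this generator; at k = 3 it reaches zero
  residual through a different (invertible-transform-related) basis, so
  factor-recovery checks for semi-NMF are run at k = 2.
* Multiplicative variants drive entries toward zero but never reach it,
  while active-set variants return exact zeros; `matrix_sparsity`'s
  `zero_tol` (default 0) should be set to a small positive value when
  measuring sparsity of multiplicative outputs.

# Reproducibility

Every stochastic routine takes an explicit seed (`fit_options(seed = )`,
or a `seed` argument) and restores the caller's RNG state. Derived seeds
(restarts, consensus runs, CV repetitions, permutations) are simple integer
offsets of the user seed, so whole experiments are reproducible from a
single integer.
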