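---
title: "Spherical rotation component analysis: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical rotation component analysis: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srca)
```

## The problem

Many biological processes are cyclic. A proliferating cell population
traverses the cell-cycle phases G1 → S → G2 → M and back to G1, so a
multivariate profile of cell-cycle regulators measured across an
asynchronous population traces out a closed curve — topologically a circle —
embedded in a high-dimensional feature space. Linear dimension reduction
(PCA) projects onto a flat subspace and cannot represent this topology; a
planar projection of a circle typically tears or overlaps the phase
ordering. `srca` instead fits a *sphere*: the data are reduced onto a
d'-dimensional sphere (a circle for d' = 1, an ordinary sphere for d' = 2)
living in a (d'+1)-dimensional coordinate subspace of a rotated frame, and
every point is represented by its hyperspherical angles on that sphere.

## Model and loss

Write the data as rows $x_1, \dots, x_n \in \mathbb{R}^d$. A fitted model
consists of an orthogonal rotation $R$, the column mean $\bar x$, an index
set $\mathcal{I} \subset \{1, \dots, d\}$ with $|\mathcal{I}| = d' + 1$, a
centre $c$ and a radius $r > 0$. In the rotated frame
$Z = (X - \bar x) R$ the sphere is

$$S_\mathcal{I}(c, r) = \{ z : \lVert (z - c)_\mathcal{I} \rVert = r,\;
  z_j = c_j \ \forall j \notin \mathcal{I} \},$$

an ordinary sphere in the coordinates $\mathcal{I}$, pinned to the centre
elsewhere. The squared distance from a point to this sphere decomposes into
an off-subspace part and an in-subspace radial part,

$$d^2(x, S_\mathcal{I}(c, r)) =
  \lVert (x - c)_{\mathcal{I}^c} \rVert^2 +
  \big( \lVert (x - c)_\mathcal{I} \rVert - r \big)^2,$$

and the fit minimizes the *geometric loss*
$\mathcal{L}(c, r, \mathcal{I}) = \sum_i d^2(x_i, S_\mathcal{I}(c, r))$
jointly over $(\mathcal{I}, c, r)$. An optional symmetric
positive-semidefinite weight matrix $W$ generalizes the quadratic forms to
$(x-c)^T W (x-c) + r^2 - 2r\sqrt{(x-c)^T W^T I_\mathcal{I} W (x-c)}$
(a Mahalanobis-flavoured loss). Note the square root: only with it is the
identity-weight case a true squared Euclidean distance, the radius update a
mean of distances, and the projection distance-attaining, so the package
uses the radical throughout, also under general $W$.

A caution on weights: if $\lambda_{\max}(W) > 1$ the weighted loss is
unbounded below as the centre recedes (the cross term outgrows the
quadratic one), so weight matrices should be scaled to spectral norm at
most 1. The package fits whatever $W$ passes validation, but the
large-radius planar initialization is disabled off the identity weight for
exactly this reason.

## The pipeline: rotate, optimize, project

1. **Rotate.** Centre the data and rotate with a data-driven orthogonal
   matrix, by default the PCA eigenbasis (descending eigenvalues, each
   column's largest-magnitude entry positive, ties kept in original order).
   The orthomax family (varimax, quartimax, equamax, parsimax, or a user
   criterion weight) rotates only the top d'+1 principal axes — the block
   that can affect the sphere fit — and leaves the complement untouched;
   ICA (fixed-point iteration, log-cosh contrast, 500 iterations at
   tolerance 1e-6, seeded) is available for strongly non-Gaussian noise.
   Factor rotations are computed from the loadings of the same matrix the
   pipeline fits; pass `standardize = TRUE` to z-score first (recommended
   for mixed-unit features).
2. **Optimize.** For a fixed index set the radius has the closed-form
   optimum $r = \frac1n \sum_i \lVert (x_i - c)_\mathcal{I} \rVert$ (its
   weighted analogue under $W$), the centre coordinates outside
   $\mathcal{I}$ have the closed form $c_j = \frac1n \sum_i x_{ij}$ (identity
   weight), and the remaining coordinates are found by backtracking gradient
   descent. The implementation interleaves the exact radius update between
   centre steps, so the radius is always at its conditional optimum and
   every accepted step decreases the loss — the returned trace is
   non-increasing by construction. Index sets are chosen by exhaustive
   enumeration when $\binom{d}{d'+1} \le 500$ and otherwise by an $\ell_1$
   relaxation (below).
3. **Project.** Each rotated point is projected radially onto the fitted
   sphere, $\hat z_j = c_j + r (z_j - c_j)/\lVert (z - c)_\mathcal{I}
   \rVert$ for $j \in \mathcal{I}$ and $\hat z_j = c_j$ otherwise, then
   mapped back to the original frame via $\hat z R^T + \bar x$. Setting the
   complement coordinates to $c_j$ (rather than zeroing them) is what makes
   the projection attain $d^2$ exactly; rows landing exactly on the centre
   of the subspace have no nearest point and are mapped deterministically to
   $c + r e_{\min \mathcal{I}}$ and flagged. The embedding reports the
   reconstruction, the unit-sphere coordinates, their hyperspherical angles
   (longitude/latitude conventions for a circle or sphere, the standard
   recursion above that, longitude 0 at poles), and per-point squared
   distances.

## Initialization and why it matters

The loss in $(c, r)$ is not convex and, on data with no spherical
structure, has multiple basins. `fit_fixed_subset()` therefore descends
from several deterministic starts and keeps the best:

* **mean** — centre at the column means, radius at its closed form;
* **spca** — centre and radius from the closed-form algebraic sphere fit
  (the linear least-squares parameterization
  $\lVert y \rVert^2 = 2 y^T c + (r^2 - \lVert c \rVert^2)$) on the
  retained coordinates; this is the two-step baseline's solution, so the
  final loss can never exceed it;
* **plane** — a sphere of radius $10^5 \times$ the data diameter tangent to
  the flattest retained coordinate, on either side. Planes are limit points
  of the sphere family as $r \to \infty$, and the best PCA plane at
  dimension d' is exactly such a limit in the PCA-rotated frame; gradient
  descent cannot reach the limit from an interior start in finite time, so
  it is supplied as a start. This makes the fitted loss at most the PCA
  reconstruction loss (and at most the two-step baseline's, via the spca
  start) *by construction*, not just asymptotically. The plane starts are
  attempted only when their initial loss already undercuts the converged
  interior fits, which is the regime they exist for;
* **ring** — the mean shifted by one standard deviation along each retained
  axis, in both directions. These reach the off-centre basins that the
  central starts miss on small unstructured samples.

The radius is capped at `r_max_factor` (default $10^6$) times the data
diameter — measured as the bounding-box diagonal, an $O(nd)$ surrogate for
the max pairwise distance — so near-planar fits stay finite; clamping is
recorded on the result. Distances are evaluated in the decomposed form
shown above rather than as $q + r^2 - 2r\sqrt{\cdot}$, because at
$r \sim 10^5$ the latter loses ten significant digits to cancellation.

## Subset search

*Exhaustive search* fits every size-(d'+1) subset and returns the smallest
loss (ties to the lexicographically smallest index set). Every subset is
first screened with a short iteration budget — each screened value is an
upper bound on that subset's optimum, since the fit only descends — and the
five best-screened subsets are then polished with the full budget. The
winner therefore always receives a complete fit, and the by-construction
dominance bounds above hold for it.

*The $\ell_1$ relaxation* replaces the binary selection vector with
$v \in [0,1]^d$, $\lVert v \rVert_1 \le d'+1$, giving radicals
$\sqrt{\sum_j v_j^2 (x_{ij} - c_j)^2}$. It runs projected gradient over
$(v, c, r)$ — exact radius updates, backtracking centre and selection steps,
Euclidean projection onto the capped simplex by bisection — from five
seeded starts, one of which weights coordinates by their centred second
moment (a deterministic, data-driven start that usually lands in the right
basin). Each start's $v$ is rounded to its d'+1 largest entries (ties to
lower indices) and the resulting subset refitted with the full fixed-subset
machinery, so the reported loss is always the loss of a valid discrete
index set and directly comparable with exhaustive search. Whether the
relaxed vector should range over $[0,1]^d$ or all of $\mathbb{R}^d$ is
ambiguous; the box keeps the selection interpretable and the projection
cheap, and the refit removes any dependence on that choice from the
returned model.

## What the synthetic generators emulate

All generators are pure functions of their parameters and seed.

* `sample_subsphere()` draws uniformly on a planted sub-sphere (normalized
  Gaussians — exact in any dimension), pins the complement at the centre,
  adds isotropic Gaussian noise (or Student-t with `noise_df` for a heavy
  tail), and optionally applies a rigid motion. This is the planted-truth
  regime behind the exact-recovery and consistency checks.
* `sample_torus()` and `sample_plane()` supply the topologically nontrivial
  and the degenerate-curvature extremes that the dominance battery needs.
* `sample_cell_cycle_like()` emulates an asynchronous proliferating
  population: contiguous phase arcs in cyclic order G1 → S → G2 → M on a
  circle in a random 2-dimensional subspace, phase fractions
  (0.5, 0.2, 0.2, 0.1) — G1-rich, M brief, as in an unsynchronized culture —
  and per-phase dispersions (0.12, 0.04, 0.08, 0.08) on a unit-radius
  circle, i.e. the G1 cluster loosest (G1 cells vary most in size and
  expression), S tightest, G2/M intermediate, at a signal-to-noise ratio
  (radius over the largest dispersion) of about 8. What it does *not*
  emulate: correlated features, phase-dependent feature loadings, batch
  structure, or the non-Gaussian marginals of real immunofluorescence
  features — so passing recovery tests here demonstrates the geometry is
  recovered under the stated noise model, not that real pipelines need no
  preprocessing.
* `srca_benchmark_battery()` packages twenty seeded datasets (noisy
  sub-spheres under rigid motions, tori, planes, clustered sphere pairs,
  heavy-tailed noise, cyclic circles; n ≤ 500, d ≤ 10, d' ∈ {1, 2}) with
  the retained dimension to use; these sizes keep a full
  fit-plus-baselines sweep around half a minute.

## Evaluation metrics

`reconstruction_mse()` is the mean squared distance between original and
reconstructed points — well-defined here because the method reconstructs in
the original space. The coranking matrix counts pairs by their
neighbour-rank in the original versus reduced space, with distance ties
broken toward the smaller index, which makes every row and column sum equal
n exactly; $Q_{NX}(K)$ is the preserved fraction of K-neighbourhoods and
$R_{NX}(K)$ its rescaling that zeroes a random embedding. The package
defines `auc` as the flat mean of $R_{NX}$ over K and `wauc` as the
1/K-weighted mean (emphasizing small neighbourhoods); both are rank-based
and hence invariant to monotone distance transforms. Cluster separation
(silhouette, Calinski-Harabasz, Davies-Bouldin) is computed on the angle
representation of spherical embeddings; angles are treated as Euclidean
coordinates, so clusters straddling the ±π seam can be penalized — a known
caveat of the angle representation, not of the fit. For cyclic structure
the package uses a circular rank correlation: both angle samples are
rank-transformed to uniform angles and the larger mean resultant length of
their differences and sums is reported, making the score invariant to
rotation and reflection of either circle, 1 for any monotone circular map
and near 0 under independence.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- sample_cell_cycle_like(n = 600, d = 12, seed = 1)
fit <- srca_fit(ds$X, retained_dim = 1)
fit

# phase order around the fitted circle
ang <- fit$embedding$angles[, 1]
circular_rank_cor(ang, ds$truth$angle)
cyclic_order_preserved(ang, ds$labels, c("G1", "S", "G2", "M"))

# against the linear and two-step baselines
c(srca = fit$mse,
  pca = pca_reduce(ds$X, 1)$mse,
  spca = spca_fit(ds$X, 1)$mse)
```

## Numerical choices and limitations

* Tolerances: orthogonality 1e-8, weight symmetry 1e-10, PSD slack -1e-10,
  relative loss convergence 1e-10, all overridable via
  `options(srca.tol.* = )` or `fit_options()`.
* Backtracking line search (shrink 0.5, sufficient decrease 1e-4) replaces
  a constant gradient step: the constants a safe constant step would need
  (bounds on the data radius, the radius cap, and the weight spectrum) are
  rarely known, while backtracking preserves the monotone-descent
  guarantee that matters.
* Degenerate rows (a point exactly at the in-subspace centre) project to a
  fixed pole and are flagged; degenerate radius updates (all points at the
  centre) are an error, not a silent zero.
* The rotation is *not* optimized jointly with the sphere — it is fixed by
  the chosen method before the search, and only the retained PCA block is
  factor-rotated. Joint optimization over the rotation is a substantially
  harder non-convex problem and out of scope.
* Automatic selection of d' is out of scope; choose it from the topology
  you expect (1 for a cycle, 2 for a spherical shell) or by comparing MSE
  across d'.
* Exhaustive search is exact over index sets but exponential in d'+1; the
  relaxation is a heuristic — the refit guarantees a valid model, not
  global optimality.
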