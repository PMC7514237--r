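---
title: "Interval-valued PCA: center, vertex, and Best Point methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-valued PCA: center, vertex, and Best Point methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(intervalpca)
```

## The data model

Symbolic interval data record, for each case $i$ and variable $j$, not a
single number but a closed interval $[a_{ij}, b_{ij}]$ carrying internal
variation — here, facial distances in pixels that vary across a sequence of
photographs of the same face.  An $n \times m$ interval matrix $X$ defines a
box of ordinary point matrices: every $Z$ with
$a_{ij} \le Z_{ij} \le b_{ij}$ is a *realization* of $X$.  Each case spans an
axis-aligned hyper-rectangle in $\mathbb{R}^m$ whose $2^{m_i}$ corners (over
its $m_i$ nontrivial intervals) are collected, case after case, in the
*vertex matrix* with $N = \sum_i 2^{m_i}$ rows.

## One PCA engine, four methods

All four methods in the package share a single engine: correlation PCA on a
realization $Z$.  Writing $\bar Z_{(j)}$ and $\sigma_{(j)}$ for the column
mean and *population* standard deviation (divisor $n$), the standardized
matrix

$$\tilde Z_{ij} = \frac{Z_{ij} - \bar Z_{(j)}}{\sqrt{n}\,\sigma_{(j)}}$$

has columns with zero mean and unit sum of squares, so
$\tilde Z^\top \tilde Z$ is exactly the correlation matrix of $Z$: its
eigenvalues $\lambda_1 \ge \dots \ge \lambda_m \ge 0$ sum to $m$, and the
orthonormal eigenvectors $w_1, \dots, w_m$ form the component basis.  The
$\sqrt{n}$ factor is what makes the row-side and column-side eigenproblems
share their nonzero spectrum (see *Duality* below); the $1/\sigma$ factor is
non-negotiable because all interval projections below standardize bounds by
the same statistics.  A covariance-scale mode is deliberately not offered.

Component *scores*, however, are reported on the conventional z-score scale
$(Z_{ij}-\bar Z_{(j)})/\sigma_{(j)}$, i.e. $\sqrt n$ times the projection of
the rows of $\tilde Z$.  The two scales describe the same geometry; the
z-score scale is the one on which published score tables for this kind of
data are printed, and the package uses it consistently for classical and
interval scores.

The methods differ only in which realization is fitted:

* **center** — $Z = X^c$, the matrix of interval midpoints
  $(a_{ij}+b_{ij})/2$;
* **vertex** — $Z$ is the full $N \times m$ vertex matrix;
* **bp-distance** — $Z_\varphi$, the realization minimizing the
  vertex-to-subspace squared distance $\varphi$;
* **bp-variance** — $Z_\Lambda$, the realization maximizing the retained
  inertia $\Lambda$.

## Interval scores without enumeration

Given a fitted basis, the score interval of case $i$ on component $k$ is the
range of the projections of the $2^{m_i}$ corners of its hyper-rectangle.
Because the projection is linear, each corner coordinate contributes
independently: the minimum takes $b_{ij}$ exactly where the loading
$w_{kj}$ is negative and $a_{ij}$ elsewhere, and the maximum swaps the
roles.  `interval_scores()` implements this sign-split closed form in
$O(nms)$; `interval_scores_bruteforce()` keeps the exponential enumeration
as an independent oracle, and the test suite asserts exact agreement
(to $10^{-10}$) on hundreds of random instances.  A loading of exactly zero
is grouped with the nonnegative side — it contributes nothing either way,
but the partition (and hence the code path) is deterministic.

Two consequences are tested as properties: every realization of the box
projects inside the intervals (containment), and widening any single
interval can only widen score intervals (monotonicity).

## Duality

For $\tilde Z$ the case-side Gram matrix $\tilde Z \tilde Z^\top$ and the
variable-side $\tilde Z^\top \tilde Z$ share their nonzero eigenvalues, with
eigenvectors linked by $u_\ell = \tilde Z^\top v_\ell / \sqrt{\lambda_\ell}$
and $v_\ell = \tilde Z u_\ell / \sqrt{\lambda_\ell}$.  `dual_components()`
builds the case-side directions sign-consistently from the fitted basis, and
`dual_scores()` returns the variable coordinates
$r_{ij} = \sum_k \tilde Z_{ki} v_{kj}$ — for the fitted matrix these are the
variable-component correlations of the correlation circle.  The dual of the
interval-score construction, `dual_interval_loadings()`, bounds $r_{ij}$
over the whole box by the same sign-split device applied along cases.

## The Best Point criteria

The center matrix is the traditional base point for interval PCA, but
nothing forces it to be the best one.  Two criteria are optimized over the
box:

* $\varphi(Z) = \sum_{v=1}^{N} \lVert \tilde x_v(Z) -
  P_{W_s} \tilde x_v(Z) \rVert^2$, the squared distance from the
  standardized vertices to the span of the first $s$ eigenvectors of $Z$'s
  correlation matrix.  Vertices are standardized by $Z$'s statistics on the
  $\sqrt n$ scale, and the subspace passes through the standardized origin
  ($Z$'s column means).  By Pythagoras $\varphi$ is total minus explained
  squared norm, which is how it is computed ($O(Nm)$ per evaluation after
  enumerating the vertices once).
* $\Lambda(Z, s) = \sum_{k \le s} \lambda_k(Z)$, the inertia retained by the
  leading components; $0 \le \Lambda \le m$.

Both are continuous on the compact box, so optima exist; both are only
piecewise-smooth (eigenvalue crossings), which drives the optimizer choice
below.

## Optimization design

The box constraint is absorbed by the reparameterization
$Z = a + t \circ (b - a)$ with $t \in [0,1]^{nm}$ (degenerate cells are
fixed), which makes the bounds uniform and scale-free.  The default solver
is box-constrained L-BFGS-B — a projected quasi-Newton with
finite-difference gradients — started, as the method definition requires, at
the center matrix $t = \tfrac12$; a cyclic coordinate-descent fallback with
golden-section line searches is available for the occasional instance where
quasi-Newton steps stall on an eigenvalue crossing.  Defaults: tolerance
$10^{-8}$ on the objective change, at most 500 iterations, one start.  With
`n_starts > 1` the extra starts are seeded random corner matrices and the
best final objective wins, ties broken by start index, so runs are exactly
reproducible.

Three safeguards matter more than the solver brand:

* iterates that would make a column constant (correlation undefined) are
  rejected through a large finite penalty;
* the returned matrix is the better of the optimizer's answer and the
  center start, so the improvement guarantees
  $\varphi(Z_\varphi) \le \varphi(X^c)$ and
  $\Lambda(Z_\Lambda) \ge \Lambda(X^c)$ hold *exactly*, not merely up to
  tolerance;
* an all-degenerate box returns its unique realization with zero
  iterations.

The retained dimension defaults to $s = 2$, the principal plane that the
rectangle plots display; tables record the $s$ actually used.  On the
27-case, 6-variable faces data the search space has 162 coordinates and a
full distance optimization takes seconds on one CPU.

## Reporting conventions

Eigenvector signs are fixed so each component's largest-magnitude loading is
positive (ties resolved toward the lower variable index) — deterministic and
idempotent.  Published tables sometimes anchor signs differently, by
requiring a named variable to load positively; `anchor_signs()` applies that
convention on request, and for correlation PCA the sign of a variable's
loading equals the sign of its correlation with the component, so anchoring
is a pure column flip.  For the faces data, anchoring PC1 so that X4 loads
positively (`anchors = c("X4", NA)`) reproduces the printed score and
correlation signs; the printed PC2 already follows the default convention.

The variable-component correlation table compares methods at vertex level:
the vertex rows are projected as supplementary points into each method's
basis and each variable's vertex column is Pearson-correlated with the
projected scores.  Because the vertex set is identical across methods, this
is the one single-number summary that is comparable between them (and it is
the definition under which the package reproduces the published correlation
table for the faces data; correlating the fitted matrix's own columns
instead gives visibly different values for the center method).  The
interval-valued alternative — dual interval loadings — is exposed
separately.

The distance table evaluates $\varphi$ at each method's fitted matrix.  The
absolute scale of published distance comparisons for the faces data depends
on an unstated choice of $s$ and standardization scale, so the package
asserts only the ordering (the distance-optimized fit is no worse than the
center), never equality to printed distance values.

## The synthetic generator

`synthesize_interval_matrix()` draws interval centers from a correlated
Gaussian with a planted two-factor loading structure (defaults: standard
normal factor scores and loadings, noise SD 0.3) and half-widths as
$|N(0, 0.5^2)|$.  The defaults emulate what matters for this method family:
a genuine low-dimensional principal subspace plus interval widths of the
same order as the noise, comparable to the relative widths of the
morphometric data.  What it does not emulate: within-case correlation
between the widths of different variables, asymmetric measurement error, or
outlying cases — so passing tests demonstrate the algebraic identities and
optimizer behaviour, not robustness of the method on messy real data.

## Numerical choices and limitations

* Tolerances: orthonormality and duality identities are asserted at
  $10^{-8}$; the sign-split/enumeration equivalence, which is exact algebra,
  at $10^{-10}$.
* Tied eigenvalues: components are ordered by descending eigenvalue, ties
  keeping the eigensolver's order; the sign convention still makes the
  result deterministic.  Exactly tied leading eigenvalues make "the first
  component" itself ill-defined, for any method of this family.
* The optimizers are local searches: there is no global-optimality claim,
  which is why comparisons against published Best Point results are stated
  as bounds relative to the center baseline (the guaranteed direction)
  rather than equalities.
* The vertex matrix is explicit ($N = \sum_i 2^{m_i}$ rows); the
  brute-force oracle is guarded at $10^6$ rows.  The closed forms make the
  *scores* cheap regardless, but $\varphi$ itself enumerates vertices and is
  exponential in the number of nontrivial intervals per case.
* Vertex rows are unweighted.  If cases differ in $m_i$, a per-case weight
  $2^{-m_i}$ could be argued; with all $m_i$ equal (as in the faces data)
  the two conventions coincide, and the unweighted form matches the
  distance criterion's plain sum over vertices.

## Worked example

```{r faces, eval = FALSE}
faces <- faces_dataset()
results <- run_comparison(faces, s = 2, anchors = c("X4", NA))
variance_table(results)
correlation_table(results)
distance_table(results)
plot_principal_plane(results[["bp-variance"]])
```

Problem sizes used throughout the package's own test suite: the 27 x 6
faces data (1728 vertex rows), random instances with up to 6 cases and 8
variables for the enumeration equivalences, and 3 x 2 to 5 x 3 boxes for the
optimizer oracles (corner enumeration and dense grid search).
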