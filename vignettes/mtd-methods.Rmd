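---
title: "Multi-threshold derivative analysis of dynamic functional networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-threshold derivative analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binary brain functional networks depend on an arbitrary choice: the
threshold at which a weighted correlation network is cut into edges and
non-edges. Classifiers built on topology at a single threshold inherit that
arbitrariness, and summaries that integrate over thresholds (area under the
property-versus-threshold curve) discard the *shape* of the change. The idea
implemented here is to keep the whole filtration: track four topological
properties as the threshold sweeps a grid, smooth each property-versus-
threshold curve, and use the sampled *first derivative* of the smoothed
curve — how fast topology is lost as the network sparsifies — as the feature
vector. We call these multi-threshold derivative (MTD) features.

## Pipeline

For one subject with an $M \times P$ region-of-interest time-series matrix:

1. **Dynamic networks.** Sliding windows of length $L$ advanced by step $s$
   give $D = \lfloor (M-L)/s \rfloor + 1$ windows; window $d$ covers
   timepoints $(d-1)s+1, \dots, (d-1)s+L$. Within each window the network is
   the Pearson correlation matrix of the columns, computed as the
   cross-product of the column-standardized window (the closed-form
   minimizer of the Frobenius fitting problem — no iterative solver is
   needed). Off-diagonal entries are Fisher $R$–$Z$ transformed,
   $z = \tfrac12 \log\frac{1+r}{1-r}$, to stabilize variance; this is on by
   default. The diagonal is fixed at 0: self-correlations are uninformative
   and would map to infinity under the transform.
2. **Threshold filtration.** Each weighted window is binarized at every
   threshold of a grid (default $0.01, 0.02, \dots, 0.35$), keeping edge
   $(i,j)$ when $|w_{ij}| > pr$. Four properties are computed per binary
   graph: mean clustering coefficient (cc), global efficiency (Eglobal),
   local efficiency (Elocal) and characteristic path length (Lp). Curves are
   averaged across windows, giving one curve per property per subject.
3. **Smoothing and differentiation.** Each curve is fit with a penalized
   cubic B-spline minimizing
   $\sum_j (y_j - c^\top\phi(t_j))^2 + \lambda \int f''(t)^2\,dt$,
   and the first derivative of the fit is sampled on the grid. The four
   35-vectors are the per-metric MTD features; their concatenation in the
   fixed order cc, Eglobal, Elocal, Lp is the fused feature (length 140).
4. **Classification.** Per cross-validation fold: features are standardized
   with training-fold statistics, selected by a cross-validated binomial
   lasso, and classified with an RBF-kernel SVM whose $(C, \Gamma)$ are
   tuned by the sparrow search algorithm (SSA) minimizing one minus the
   inner cross-validated accuracy — all fit on the training portion only.
   Reported metrics are ACC, SEN, SPE and rank-based AUC as mean ± sd over
   folds (× repeats).

## Conventions on degenerate graphs

Thresholding signed Fisher-transformed weights requires a sign policy that
the binary-network literature rarely states explicitly; we default to
magnitude thresholding ($|w| > pr$), with signed mode available
(`use_absolute = FALSE`). Other conventions, all exercised by closed-form
tests:

* Lp averages shortest-path lengths over mutually reachable ordered pairs
  only; a graph with no reachable pair returns 0. The
  unreachable-pairs-as-zero-efficiency convention already lives in Eglobal,
  so Lp does not need an infinity convention of its own.
* Nodes with fewer than two neighbours contribute 0 to cc and Elocal
  (Brain Connectivity Toolbox convention).
* Empty graphs return (0, 0, 0, 0).

The metric kernels are compiled (breadth-first shortest paths and triangle
counting in C++); the test suite checks them against brute-force
Floyd–Warshall and triple-enumeration oracles to $10^{-12}$ on random
graphs, and against igraph as a second opinion.

## Spline choices

The basis is cubic (order 4) with `n_basis = 10` functions for the default
35-point grid, interior knots at equally spaced quantiles of the grid. The
roughness penalty is the integrated squared *second* derivative, the
standard functional-data-analysis reading of curve roughness; its Gram
matrix is assembled exactly by 3-point Gauss–Legendre quadrature per knot
span (the integrand is piecewise quadratic, so the quadrature is exact).
$\lambda$ defaults to per-curve generalized cross-validation over the
ladder $10^{-6}, \dots, 10^{2}$; because GCV sees one subject's curve and
never the group labels, it cannot leak label information across
cross-validation folds. With $\lambda = 0$ and a square basis the fit
interpolates (residual sum of squares below $10^{-10}$ in tests); as
$\lambda \to \infty$ the fit tends to a straight line. The unpenalized
system with more basis functions than points is refused with guidance
rather than silently regularized.

## SSA choices

The paper-facing update rules are implemented literally: discoverers shrink
by $\exp(-i/(\alpha T))$ in safe conditions ($R_2 < ST$) and take normal
perturbations otherwise; starving followers (rank $> n/2$) resample around
$\Gamma \exp(X_w - X_i)$ per dimension; the remaining followers move to the
best discoverer plus the $|X_i - X_p| A^+ Z$ correction, where
$A^+ = A^\top/d$ for a random $\pm 1$ row vector so the correction is a
scalar step; alerters jump toward the best position via
$X_b + \beta(X_i - X_b)$ unless already there, in which case they move by
$K (X_i - X_w)/(|f_i - f_w| + \delta)$ with $\delta$ preventing division by
zero. All positions are clamped to the bounds and an elitist incumbent is
kept, so the best-so-far trace is non-increasing by construction.

Choices the source material leaves open, fixed here once: minimization of
$1 - $ inner-CV accuracy as the tuning fitness; $(C, \Gamma)$ searched in
$\log_{10}$ space over $C \in [10^{-2}, 10^{3}]$,
$\Gamma \in [10^{-4}, 10]$; population defaults $n = 20$, $T = 50$,
discoverer fraction 0.2, alerter fraction 0.15, $ST = 0.8$ (the alerter
fraction and $ST$ intervals follow the stated 10–20% and $[0.5, 1]$
ranges). Inside cross-validation the per-fold tuning budget defaults to a
smaller $n = 8$, $T = 8$ with 3 inner folds: the 2-D tuning problem is
cheap and flat enough that a compact population finds the same plateau,
and the budget keeps repeated CV affordable.

## The synthetic cohort

Patient resting-state fMRI in this setting is private, so all evaluation
uses a generator whose ground truth is known. Subjects are zero-mean
multivariate normal time series whose correlation matrix is modular:
`intra_corr` within modules (default 0.6), `inter_corr` between (default
0.1), unit diagonal, positive definiteness verified by the smallest
eigenvalue. The planted group difference reduces `intra_corr` by `effect`
in the positive group, emulating weakened within-module connectivity;
controls therefore sit above positives on integration/segregation curves,
matching the qualitative group ordering the framework is designed to
detect. Defaults are desk scale — $P = 20$ regions in 4 modules,
$M = 100$ timepoints, cohorts of 40 + 40 — with $P = 90$ available to
mirror a standard anatomical atlas. An optional AR(1) coefficient adds
temporal smoothness while preserving the spatial covariance
(innovations scaled by $\sqrt{1-\phi^2}$); it is off by default because
the pipeline consumes only correlation structure and temporally white
draws make Monte-Carlo oracles exact.

What the generator does *not* emulate: hemodynamic response convolution,
scanner drift and motion artefacts, spatially heterogeneous noise,
non-stationary (state-switching) connectivity. Passing tests therefore
demonstrate internal correctness and calibration of the framework, not
clinical performance on real fMRI.

## Calibration and power, as tested

The acceptance suite runs the full pipeline at the desk scale above:

* **Null calibration** — with `effect = 0` and repeated stratified 10-fold
  CV, mean accuracy must fall inside the 95% binomial band around 0.5 for
  80 subjects, i.e. $(0.390,\ 0.610)$. Cross-validated accuracy under the
  null sits slightly *below* 0.5 on average (a known small-sample effect of
  stratified CV), which the band accommodates.
* **Power** — with `effect = 0.3`, mean 10-fold CV accuracy over 10 cohort
  seeds must exceed 0.75, and the fused feature must be at least as
  accurate as the best single-metric feature in a majority of seeds. At
  this effect size the synthetic separation is strong and accuracy
  saturates near 1, so the fused-versus-single comparison is dominated by
  ties — the ordering claim is preserved, not sharpened, by these
  conditions.
* **No leakage** — per-fold standardization statistics, lasso support and
  tuned $(C, \Gamma)$ are bit-identical under permutation of the held-out
  fold's labels.

Problem sizes in the tests (cohorts of 24–80 subjects, $P \le 20$,
reduced SSA budgets inside CV) are the package's chosen test scale; the
same code paths run unchanged at atlas scale.

## Known limitations

* The t-test on fused features reduces each subject's vector to a scalar
  (mean by default, first principal score optionally); a single p-value
  necessarily hides which thresholds drive the difference.
* Area, single-threshold and edge-weight baselines are provided for
  comparison, but no persistent-homology or other literature baselines.
* The sweep harness reports the best step per window length by default
  (mirroring how such tables are usually printed); full grids are a flag
  away.
* Proportional (density-based) thresholding and weighted-graph metric
  variants are out of scope.
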