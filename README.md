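# mtdnet

Multi-threshold derivative (MTD) analysis of dynamic brain functional
networks, with an SSA-tuned SVM classification pipeline and a synthetic
two-group cohort generator for end-to-end evaluation.

## The problem

Binary brain-network analysis hinges on an arbitrary binarization
threshold: cut a weighted correlation network too low and everything is
connected, too high and it shatters. Classifying subjects from topology at
one threshold inherits that arbitrariness; integrating topology over
thresholds (area under the curve) hides *how* the network degrades.
`mtdnet` keeps the whole filtration. For each subject it tracks four
topological properties — mean clustering coefficient (cc), global
efficiency (Eglobal), local efficiency (Elocal) and characteristic path
length (Lp) — across a grid of absolute thresholds, smooths each
property-versus-threshold curve with a penalized cubic B-spline

$$\min_c \sum_j \left(y_j - c^\top\phi(t_j)\right)^2 + \lambda \int f''(t)^2\,dt,$$

and uses the first derivative of the smoothed curve, sampled on the grid,
as the feature vector: the multi-threshold derivative. The four per-metric
MTD vectors (35 values each on the default 0.01–0.35 grid) are
concatenated into a fused 140-dimensional feature.

The upstream networks are sliding-window Pearson correlation matrices
($D = \lfloor (M-L)/s\rfloor + 1$ windows of length $L$, step $s$) with
Fisher $R$–$Z$ stabilization $z = \tfrac12\log\frac{1+r}{1-r}$.
Downstream, features are standardized and lasso-selected per
cross-validation fold, and an RBF-kernel SVM is tuned per fold by the
sparrow search algorithm (SSA), a three-role swarm optimizer, minimizing
inner cross-validated error over $C \in [10^{-2},10^3]$,
$\Gamma \in [10^{-4},10]$ in log space. Reports carry fold-wise
ACC/SEN/SPE and rank-based AUC as mean ± sd.

Patient fMRI in this setting is private, so the package ships a
synthetic-cohort generator: multivariate normal time series with modular
covariance (within-module correlation 0.6, between 0.1 by default), where
the positive group's within-module correlation is reduced by a
controllable `effect` — weakened integration/segregation with known ground
truth. Who this is for: researchers who want threshold-filtration features
for connectivity classification with a calibrated, fully reproducible test
bed, rather than a pipeline validated only on inaccessible data.

## Worked example

```r
library(mtdnet)

spec   <- covariance_spec(20, n_modules = 4, intra_corr = 0.6, inter_corr = 0.1)
cohort <- generate_cohort(n_pos = 20, n_ctrl = 20, M = 100,
                          base_spec = spec, effect = 0.3, seed = 42)
cohort
#> mtd_cohort: 20 positive + 20 control subjects, 100 x 20 series (seed 42)

prep <- cohort_curves(cohort, L = 85, s = 3)   # 6 windows, 35 thresholds
X    <- recipe_features(prep, "mtd_fused")     # 40 x 140 feature matrix

report <- cross_validate(X, prep$labels, k = 10, seed = 42)
report
#> ACC 100.00% +/- 0.00 | SEN 100.00% +/- 0.00 | SPE 100.00% +/- 0.00 | AUC 1.0000 +/- 0.0000  (10 folds)

mtd   <- extract_mtd(prep$curves)
fused <- lapply(mtd, function(f) fuse_features(f[c("cc","Eglobal","Elocal","Lp")]))
gd    <- group_difference_test(fused, prep$labels)
sprintf("t = %.2f, p = %.3g", gd$t_statistic, gd$p_value)
#> "t = -7.94, p = 1.13e-08"
```

At `effect = 0.3` the planted connectivity difference is strong: repeated
10-fold cross-validation separates the groups perfectly, and the
two-sample t-test on the fused MTD summary is far below 0.05 (negative t:
the positive group's curves, and hence derivative summaries, sit below the
controls'). With `effect = 0` the same pipeline stays at chance — that
calibration is asserted by the test suite.

Feature-weight attribution over the fused layout uses the lasso
coefficients:

```r
sel <- lasso_select(scale(X), prep$labels, seed = 42)
w <- numeric(ncol(X)); w[sel$indices] <- sel$coefficients
round(feature_weight_percentages(w), 1)
#>      cc Eglobal  Elocal      Lp
#>    47.6     0.0    52.4     0.0
```

Baselines (`"area"`, `"traditional"`, `"edges"`, single-metric
`"mtd_cc"`, ...) and window/threshold sweeps run through
`run_comparison()` and `parameter_sweep()` on identical fold assignments,
so recipe comparisons are paired. A thin command-line front end with
`simulate` / `build-networks` / `curves` / `mtd` / `classify` / `sweep`
subcommands lives in `inst/cli/mtdnet.R`.

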