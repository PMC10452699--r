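test_that("area features are trapezoidal integrals of the curves", {
  prep <- tiny_prep()
  cs <- prep$curves[[1]]
  # constant curve: rectangle rule
  cs_const <- cs
  cs_const$curves[, "cc"] <- 0.7
  a <- area_features(cs_const)
  width <- max(cs$thresholds) - min(cs$thresholds)
  expect_equal(unname(a["cc"]), 0.7 * width, tolerance = 1e-12)
  # linear curve: closed form
  cs_lin <- cs
  cs_lin$curves[, "Lp"] <- 2 - 3 * cs$thresholds
  a2 <- area_features(cs_lin)
  t0 <- min(cs$thresholds); t1 <- max(cs$thresholds)
  closed <- 2 * (t1 - t0) - 1.5 * (t1^2 - t0^2)
  expect_equal(unname(a2["Lp"]), closed, tolerance = 1e-12)
  # random curve vs a fine Riemann refinement of the same piecewise-linear
  # interpolant
  f <- approxfun(cs$thresholds, cs$curves[, "Eglobal"])
  tt <- seq(min(cs$thresholds), max(cs$thresholds), length.out = 20001)
  # average of left and right Riemann sums on a fine refinement
  riemann <- sum((f(tt[-1]) + f(tt[-length(tt)])) / 2 * diff(tt))
  expect_equal(unname(area_features(cs)["Eglobal"]), riemann,
               tolerance = 1e-6)
})

test_that("area features integrate the MTD derivative back to curve increments", {
  prep <- tiny_prep()
  cs <- prep$curves[[1]]
  # fundamental theorem on the smoothed curve: integral of f' over the grid
  # equals f(high) - f(low)
  fit <- fit_penalized_spline(cs$thresholds, cs$curves[, "cc"], n_basis = 7,
                              penalty = 1e-6)
  d <- derivative_curve(fit, seq(min(cs$thresholds), max(cs$thresholds),
                                 length.out = 201))
  integral <- pracma::trapz(d$grid, d$values)
  increment <- eval_spline(fit, max(cs$thresholds)) -
    eval_spline(fit, min(cs$thresholds))
  expect_equal(integral, increment, tolerance = 1e-3)
})

test_that("traditional features restrict the curves to one threshold", {
  prep <- tiny_prep()
  pr <- prep$grid$values[3]
  tf <- traditional_features(prep$networks[[1]], pr)
  expect_equal(unname(tf), unname(prep$curves[[1]]$curves[3, ]),
               tolerance = 1e-12)
  # complete- and empty-graph limits
  W <- prep$networks[[1]]$windows[[1]]
  lo <- min(abs(W[upper.tri(W)])) / 2
  tf_lo <- traditional_features(prep$networks[[1]], max(lo, 1e-6))
  hi <- max(abs(W)) + 10
  tf_hi <- traditional_features(prep$networks[[1]], hi)
  expect_equal(unname(tf_hi), c(0, 0, 0, 0))
  expect_true(all(tf_lo <= 1 + 1e-12))
})

test_that("edge features vectorize the upper triangle deterministically", {
  prep <- tiny_prep(P = 4)
  e <- edge_features(prep$networks[[1]])
  expect_length(e, 6)
  W <- mean_network(prep$networks[[1]])
  expect_equal(e, W[upper.tri(W)])
  e2 <- edge_features(prep$networks[[1]])
  expect_identical(e, e2)
})

test_that("recipe matrices have consistent dimensions per subject", {
  prep <- tiny_prep()
  n <- length(prep$curves)
  expect_identical(dim(recipe_features(prep, "area")), c(n, 4L))
  expect_identical(dim(recipe_features(prep, "traditional")), c(n, 4L))
  expect_identical(dim(recipe_features(prep, "edges")),
                   c(n, as.integer(10 * 9 / 2)))
  expect_identical(ncol(recipe_features(prep, "mtd_cc", n_basis = 7)),
                   length(prep$grid$values))
  expect_error(recipe_features(prep, "nope"), "unknown recipe")
})

test_that("single-recipe comparison reduces to cross_validate on shared folds", {
  co <- generate_cohort(8, 8, M = 60,
                        base_spec = covariance_spec(10, 2, 0.6, 0.1),
                        effect = 0.3, seed = 31)
  cmp <- run_comparison(co, recipes = "mtd_fused", L = 40, s = 10,
                        grid = threshold_grid(0.05, 0.35, 0.05),
                        k = 4, seed = 9, svm_tuning = fast_tuning,
                        n_basis = 7)
  prep <- cohort_curves(co, L = 40, s = 10,
                        grid = threshold_grid(0.05, 0.35, 0.05))
  X <- recipe_features(prep, "mtd_fused", n_basis = 7)
  direct <- cross_validate(X, prep$labels, k = 4, seed = 9,
                           svm_tuning = fast_tuning,
                           folds = cmp$fold_assignments)
  expect_equal(cmp$reports$mtd_fused$folds, direct$folds)
})

test_that("paired comparisons share identical fold assignments across recipes", {
  co <- generate_cohort(6, 6, M = 60,
                        base_spec = covariance_spec(8, 2, 0.6, 0.1),
                        effect = 0.3, seed = 77)
  cmp <- run_comparison(co, recipes = c("area", "edges"), L = 40, s = 10,
                        grid = threshold_grid(0.05, 0.35, 0.1),
                        k = 3, seed = 5, svm_tuning = fast_tuning)
  expect_identical(cmp$reports$area$fold_assignments,
                   cmp$reports$edges$fold_assignments)
  expect_identical(nrow(cmp$table), 2L)
})

test_that("parameter sweeps enumerate configurations and skip impossible ones", {
  co <- generate_cohort(6, 6, M = 60,
                        base_spec = covariance_spec(8, 2, 0.6, 0.1),
                        effect = 0.3, seed = 55)
  ranges <- list(c(0.05, 0.2), c(0.05, 0.35))
  tab <- parameter_sweep(co, L_values = c(40), s_values = c(10),
                         threshold_ranges = ranges, grid_step = 0.05,
                         recipe = "area", k = 3, seed = 2,
                         svm_tuning = fast_tuning)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("L", "s", "thr_low", "thr_high", "ACC") %in% names(tab)))

  expect_warning(
    tab2 <- parameter_sweep(co, L_values = c(40, 100), s_values = c(10),
                            threshold_ranges = ranges[2], grid_step = 0.05,
                            recipe = "area", k = 3, seed = 2,
                            svm_tuning = fast_tuning),
    "skipping L = 100")
  expect_identical(nrow(tab2), 1L)

  # determinism under a fixed master seed
  tab3 <- parameter_sweep(co, L_values = c(40), s_values = c(10),
                          threshold_ranges = ranges[1], grid_step = 0.05,
                          recipe = "area", k = 3, seed = 2,
                          svm_tuning = fast_tuning)
  expect_equal(tab3$ACC, tab[tab$thr_high == 0.2, "ACC"])
})

test_that("report and curve tables round-trip to delimited files", {
  dir <- withr::local_tempdir()
  prep <- tiny_prep(n_per = 3)
  long <- curves_long_table(prep$curves)
  expect_identical(nrow(long), 6L * 4L * length(prep$grid$values))
  p <- file.path(dir, "curves.tsv")
  write_metric_curves(prep$curves[[1]], p)
  back <- read.delim(p)
  expect_equal(back$cc, unname(prep$curves[[1]]$curves[, "cc"]),
               tolerance = 1e-6)

  X <- recipe_features(prep, "area")
  rownames(X) <- vapply(prep$curves, `[[`, character(1), "subject_id")
  fp <- file.path(dir, "features.tsv")
  write_feature_table(X, fp, hyper = list(n_basis = 7, penalty = "gcv"))
  expect_true(file.exists(paste0(fp, ".params")))
  fb <- read.delim(fp)
  expect_identical(nrow(fb), nrow(X))
})
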