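grid35 <- threshold_grid(0.01, 0.35, 0.01)$values

test_that("unpenalized fit with a square basis interpolates the data", {
  set.seed(1)
  y <- rnorm(35)
  fit <- fit_penalized_spline(grid35, y, n_basis = 35, penalty = 0)
  expect_lt(fit$rss, 1e-10)
  expect_error(fit_penalized_spline(grid35, y, n_basis = 40, penalty = 0),
               "singular")
})

test_that("a huge penalty drives the fit to a straight line", {
  y <- sin(8 * grid35)
  fit <- fit_penalized_spline(grid35, y, n_basis = 12, penalty = 1e8)
  expect_lt(spline_roughness(fit), 1e-6)
  # straight line: second derivative ~ 0 everywhere
  expect_lt(max(abs(eval_spline(fit, grid35, deriv = 2L))), 1e-2)
})

test_that("curves inside the spline space are recovered under moderate smoothing", {
  y <- grid35^2
  fit <- fit_penalized_spline(grid35, y, n_basis = 10, penalty = 1e-6)
  expect_lt(max(abs(fit$fitted - y)), 1e-3)
})

test_that("roughness decreases and residual error grows along a lambda ladder", {
  set.seed(7)
  y <- sin(10 * grid35) + rnorm(35, sd = 0.05)
  ladder <- 10^seq(-8, 4, length.out = 13)
  fits <- lapply(ladder, function(l) {
    fit_penalized_spline(grid35, y, n_basis = 12, penalty = l)
  })
  rough <- vapply(fits, spline_roughness, numeric(1))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  expect_true(all(diff(rough) <= 1e-8))
  expect_true(all(diff(rss) >= -1e-10))
})

test_that("derivative curves match analytic derivatives", {
  # linear
  fit <- fit_penalized_spline(grid35, 3 * grid35 + 1, n_basis = 8,
                              penalty = 1e-8)
  d <- derivative_curve(fit, grid35)
  expect_lt(max(abs(d$values - 3)), 1e-6)
  # constant
  fitc <- fit_penalized_spline(grid35, rep(2, 35), n_basis = 8,
                               penalty = 1e-8)
  expect_lt(max(abs(derivative_curve(fitc, grid35)$values)), 1e-6)
  # sin/cos on the interior
  fits <- fit_penalized_spline(grid35, sin(grid35), n_basis = 10,
                               penalty = 1e-8)
  ds <- derivative_curve(fits, grid35)
  interior <- 4:32
  expect_lt(max(abs(ds$values[interior] - cos(grid35[interior]))), 1e-2)
  # evaluation outside the domain is refused
  expect_error(eval_spline(fits, 0.5), "outside the fit domain")
})

test_that("derivative is linear in the fitted coefficients", {
  set.seed(3)
  y1 <- rnorm(35); y2 <- rnorm(35)
  f1 <- fit_penalized_spline(grid35, y1, n_basis = 10, penalty = 1e-3)
  f2 <- fit_penalized_spline(grid35, y2, n_basis = 10, penalty = 1e-3)
  f12 <- fit_penalized_spline(grid35, 2 * y1 - 0.5 * y2, n_basis = 10,
                              penalty = 1e-3)
  expect_equal(f12$coefficients, 2 * f1$coefficients - 0.5 * f2$coefficients,
               tolerance = 1e-8)
  expect_equal(derivative_curve(f12, grid35)$values,
               2 * derivative_curve(f1, grid35)$values -
                 0.5 * derivative_curve(f2, grid35)$values,
               tolerance = 1e-6)
})

test_that("MTD extraction yields one 35-vector per metric and is order-invariant", {
  prep <- tiny_prep()
  mtd <- extract_mtd(prep$curves, n_basis = 8)
  expect_length(mtd, length(prep$curves))
  expect_length(mtd[[1]]$cc$values, length(prep$grid$values))
  # identical curves give identical features
  mtd_dup <- extract_mtd(prep$curves[c(1, 1)], n_basis = 8)
  expect_identical(mtd_dup[[1]]$Lp$values, mtd_dup[[2]]$Lp$values)
  # subject order does not change any subject's features
  rev_mtd <- extract_mtd(rev(prep$curves), n_basis = 8)
  expect_identical(mtd[[1]]$cc$values,
                   rev_mtd[[length(rev_mtd)]]$cc$values)
  # mismatched grids are rejected
  bad <- prep$curves
  bad[[2]]$thresholds <- bad[[2]]$thresholds + 0.001
  expect_error(extract_mtd(bad), "share one threshold grid")
})

test_that("fusion concatenates the four metrics in fixed order", {
  prep <- tiny_prep()
  mtd <- extract_mtd(prep$curves, n_basis = 8)
  f <- fuse_features(mtd[[1]][c("cc", "Eglobal", "Elocal", "Lp")])
  expect_identical(f$metric, "fused")
  expect_length(f$values, 4 * length(prep$grid$values))
  expect_identical(f$values[seq_along(prep$grid$values)],
                   mtd[[1]]$cc$values)
  expect_error(fuse_features(mtd[[1]][c("Eglobal", "cc", "Elocal", "Lp")]),
               "order")
  expect_error(fuse_features(mtd[[1]]["cc"]), "four")
  mixed <- mtd[[1]]; mixed$Lp$subject_id <- "someone_else"
  expect_error(fuse_features(mixed[c("cc", "Eglobal", "Elocal", "Lp")]),
               "one subject")
})

test_that("feature matrices lay subjects out in rows with block columns", {
  prep <- tiny_prep()
  mtd <- extract_mtd(prep$curves, n_basis = 8)
  Xf <- mtd_feature_matrix(mtd, "fused")
  expect_identical(dim(Xf), c(8L, 28L))  # 8 subjects, 4 x 7 grid points
  Xc <- mtd_feature_matrix(mtd, "cc")
  expect_identical(unname(Xf[, 1:7]), unname(Xc))
})

test_that("group difference testing behaves like a two-sample t-test", {
  X <- rbind(matrix(1:3, 3, 1), matrix(1:3, 3, 1))
  labs <- c(rep("positive", 3), rep("control", 3))
  res <- group_difference_test(X, labs)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(12)
  Xs <- rbind(matrix(rnorm(40 * 5, mean = 1), 40),
              matrix(rnorm(40 * 5, mean = 0), 40))
  labs2 <- c(rep("positive", 40), rep("control", 40))
  res2 <- group_difference_test(Xs, labs2)
  expect_lt(res2$p_value, 0.05)

  flipped <- group_difference_test(Xs, ifelse(labs2 == "positive",
                                              "control", "positive"))
  expect_equal(flipped$t_statistic, -res2$t_statistic, tolerance = 1e-12)
  expect_equal(flipped$p_value, res2$p_value, tolerance = 1e-12)

  expect_error(group_difference_test(Xs[1:41, ], labs2[1:41]),
               "2 subjects per group")
})
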