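test_that("binarization compares weights (or their magnitudes) to the threshold", {
  W <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_identical(binarize(W, 0.35)[1, 2], 1L)
  expect_identical(binarize(W, 0.5)[1, 2], 0L)
  Wn <- matrix(c(0, -0.4, -0.4, 0), 2)
  expect_identical(binarize(Wn, 0.35)[1, 2], 1L)                      # |w| mode
  expect_identical(binarize(Wn, 0.35, use_absolute = FALSE)[1, 2], 0L) # signed

  set.seed(5)
  W <- rand_weighted_network(8)
  lo <- min(abs(W[upper.tri(W)])) / 2
  hi <- max(abs(W)) + 0.1
  expect_identical(binarize(W, lo), complete_graph(8))
  expect_identical(binarize(W, hi), matrix(0L, 8, 8))

  Wbad <- W; Wbad[1, 2] <- Wbad[1, 2] + 1
  expect_error(binarize(Wbad, 0.1), "symmetric")
})

test_that("closed-form graphs give the known metric values", {
  K4 <- complete_graph(4)
  expect_equal(unname(graph_metrics(K4)), c(1, 1, 1, 1))
  P3 <- path_graph(3)
  expect_equal(clustering_coefficient(P3), 0)
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_equal(local_efficiency(P3), 0)
  expect_equal(characteristic_path_length(P3), 4 / 3)
  K3 <- complete_graph(3)
  expect_equal(clustering_coefficient(K3), 1)
  # star: centre's neighbourhood is edgeless, leaves have degree 1
  star <- matrix(0L, 4, 4); star[1, 2:4] <- 1L; star <- star + t(star)
  expect_equal(local_efficiency(star), 0)
  expect_equal(clustering_coefficient(star), 0)
  # empty graph conventions
  E <- matrix(0L, 5, 5)
  expect_equal(unname(graph_metrics(E)), c(0, 0, 0, 0))
  # two disjoint edges: only reachable pairs enter Lp
  D2 <- matrix(0L, 4, 4); D2[1, 2] <- D2[2, 1] <- D2[3, 4] <- D2[4, 3] <- 1L
  expect_equal(characteristic_path_length(D2), 1)
})

test_that("all four metrics agree with brute-force enumeration on random graphs", {
  set.seed(101)
  for (rep in 1:120) {
    P <- sample(4:12, 1)
    A <- rand_binary_graph(P, p_edge = runif(1, 0.1, 0.7))
    expect_equal(clustering_coefficient(A), oracle_cc(A), tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_eglobal(A), tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_elocal(A), tolerance = 1e-12)
    expect_equal(characteristic_path_length(A), oracle_lp(A),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph's implementations as a second opinion", {
  set.seed(2024)
  for (rep in 1:20) {
    A <- rand_binary_graph(10, p_edge = 0.35)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(clustering_coefficient(A),
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"), tolerance = 1e-12)
    expect_equal(global_efficiency(A), igraph::global_efficiency(g),
                 tolerance = 1e-12)
    lp_ig <- igraph::mean_distance(g, unconnected = TRUE)
    if (!is.nan(lp_ig)) {
      expect_equal(characteristic_path_length(A), lp_ig, tolerance = 1e-12)
    }
  }
})

test_that("metric bounds hold across random graphs", {
  set.seed(303)
  for (rep in 1:50) {
    A <- rand_binary_graph(sample(3:12, 1), p_edge = runif(1, 0, 1))
    m <- graph_metrics(A)
    expect_gte(m[["cc"]], 0); expect_lte(m[["cc"]], 1)
    expect_gte(m[["Eglobal"]], 0); expect_lte(m[["Eglobal"]], 1)
    expect_gte(m[["Elocal"]], 0); expect_lte(m[["Elocal"]], 1)
    if (sum(A) > 0) expect_gte(m[["Lp"]], 1) else expect_equal(m[["Lp"]], 0)
  }
})

test_that("edge count and global efficiency are non-increasing along the filtration", {
  set.seed(99)
  grid <- threshold_grid(0.01, 0.8, 0.02)
  for (rep in 1:50) {
    W <- rand_weighted_network(12)
    edges <- numeric(length(grid$values))
    eg <- numeric(length(grid$values))
    for (k in seq_along(grid$values)) {
      A <- binarize(W, grid$values[k])
      edges[k] <- sum(A) / 2
      eg[k] <- global_efficiency(A)
    }
    expect_true(all(diff(edges) <= 0))
    expect_true(all(diff(eg) <= 1e-12))
  }
})

test_that("threshold grids enumerate low..high by step", {
  g <- threshold_grid(0.01, 0.35, 0.01)
  expect_length(g$values, 35)
  expect_equal(g$values[1], 0.01)
  expect_equal(g$values[35], 0.35, tolerance = 1e-9)
  expect_true(all(diff(g$values) > 0))
  expect_error(threshold_grid(0, 0.3, 0.01))
})

test_that("metric curves aggregate windows and keep grid geometry", {
  s <- sample_subject(build_covariance(covariance_spec(10, 2, 0.6, 0.1)),
                      M = 80, seed = 8)
  net <- build_dbfn(s, make_window_scheme(80, 60, 10))
  grid <- threshold_grid(0.01, 0.35, 0.01)
  cs <- metric_curves(net, grid)
  expect_identical(dim(cs$curves), c(35L, 4L))
  expect_true(all(is.finite(cs$curves)) && all(cs$curves >= 0))

  # single window: curves equal the per-window metrics directly
  net1 <- structure(list(subject_id = "x", windows = net$windows[1],
                         fisher_applied = TRUE), class = "dynamic_network")
  cs1 <- metric_curves(net1, grid)
  k <- 10
  expect_equal(unname(cs1$curves[k, ]),
               unname(graph_metrics(binarize(net$windows[[1]],
                                             grid$values[k]))),
               tolerance = 1e-12)

  # duplicating identical windows leaves the mean curve unchanged
  net2 <- structure(list(subject_id = "x",
                         windows = c(net$windows[1], net$windows[1]),
                         fisher_applied = TRUE), class = "dynamic_network")
  expect_equal(metric_curves(net2, grid)$curves, cs1$curves,
               tolerance = 1e-12)

  # per-window aggregation retains the full array and its mean matches
  csw <- metric_curves(net, grid, aggregation = "per-window")
  expect_identical(dim(csw$per_window), c(3L, 35L, 4L))
  expect_equal(apply(csw$per_window, c(2, 3), mean), unname(cs$curves),
               tolerance = 1e-12, ignore_attr = TRUE)
})
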