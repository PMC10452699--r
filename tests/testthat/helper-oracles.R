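# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package (Floyd-Warshall instead of BFS, explicit
# triple/pair enumeration instead of adjacency-list traversal, two-pass
# moments instead of a standardized cross-product).

oracle_distances <- function(A) {
  P <- nrow(A)
  D <- matrix(Inf, P, P)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(P)) {
    for (i in seq_len(P)) {
      for (j in seq_len(P)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_cc <- function(A) {
  P <- nrow(A)
  if (P == 0) return(0)
  ci <- numeric(P)
  for (i in seq_len(P)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] != 0) tri <- tri + 1
      }
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  vals <- D[row(D) != col(D)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

oracle_eglobal <- function(A) {
  P <- nrow(A)
  if (P < 2) return(0)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    }
  }
  s / (P * (P - 1))
}

oracle_elocal <- function(A) {
  P <- nrow(A)
  if (P == 0) return(0)
  vals <- numeric(P)
  for (i in seq_len(P)) {
    nb <- which(A[i, ] != 0)
    if (length(nb) >= 2) vals[i] <- oracle_eglobal(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# two-pass Pearson correlation of two vectors
oracle_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

rand_binary_graph <- function(P, p_edge = 0.3) {
  A <- matrix(0L, P, P)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p_edge)
  A + t(A)
}

rand_weighted_network <- function(P) {
  W <- matrix(stats::runif(P * P, -1, 1), P, P)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

path_graph <- function(P) {
  A <- matrix(0L, P, P)
  for (i in seq_len(P - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

complete_graph <- function(P) {
  A <- matrix(1L, P, P)
  diag(A) <- 0L
  A
}

# tiny preassembled cohort -> curves for feature-level tests
tiny_prep <- function(n_per = 4, P = 10, M = 60, effect = 0.3, seed = 11,
                      L = 40, s = 10) {
  co <- generate_cohort(n_per, n_per, M = M,
                        base_spec = covariance_spec(P, 2, 0.6, 0.1),
                        effect = effect, seed = seed)
  cohort_curves(co, L = L, s = s, grid = threshold_grid(0.05, 0.35, 0.05))
}

fast_tuning <- list(inner_k = 2L, n_sparrows = 4L, max_iter = 3L)
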