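#' Configuration for the sparrow search algorithm
#'
#' Population metaheuristic with three behavioural roles: discoverers
#' (best-ranked sparrows, wide search), followers (track the best
#' discoverer or scatter when starving) and alerters (a random 10-20%
#' subset that reacts to danger each iteration). Used here to tune SVM
#' hyperparameters, but the optimizer is generic over box-constrained
#' objectives under a minimization convention.
#'
#' @param dimensions Problem dimensionality d.
#' @param bounds d x 2 matrix of finite `[low, high]` box constraints (a
#'   length-2 vector is recycled over dimensions).
#' @param n_sparrows Population size n.
#' @param max_iter Iteration budget T.
#' @param discoverer_fraction Fraction of the population acting as
#'   discoverers.
#' @param alerter_fraction Fraction acting as alerters each iteration, in
#'   `[0.10, 0.20]`.
#' @param safety_threshold Safety value ST in `[0.5, 1]` against which the
#'   random alarm R2 is compared.
#' @param delta Small constant preventing division by zero in the alerter
#'   update.
#' @param seed Integer seed controlling every random draw of a run.
#' @return An object of class `ssa_config`.
#' @export
ssa_config <- function(dimensions, bounds, n_sparrows = 20L, max_iter = 50L,
                       discoverer_fraction = 0.2, alerter_fraction = 0.15,
                       safety_threshold = 0.8, delta = 1e-8, seed = 1L) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, nrow = dimensions,
                                             ncol = 2, byrow = TRUE)
  stopifnot(nrow(bounds) == dimensions, ncol(bounds) == 2,
            all(is.finite(bounds)), all(bounds[, 1] < bounds[, 2]),
            discoverer_fraction > 0, discoverer_fraction < 1,
            alerter_fraction >= 0.10, alerter_fraction <= 0.20,
            safety_threshold >= 0.5, safety_threshold <= 1,
            n_sparrows >= 2, max_iter >= 1, delta > 0)
  structure(list(dimensions = as.integer(dimensions), bounds = bounds,
                 n_sparrows = as.integer(n_sparrows),
                 max_iter = as.integer(max_iter),
                 discoverer_fraction = discoverer_fraction,
                 alerter_fraction = alerter_fraction,
                 safety_threshold = safety_threshold,
                 delta = delta, seed = as.integer(seed)),
            class = "ssa_config")
}

clamp_bounds <- function(X, bounds) {
  for (j in seq_len(ncol(X))) {
    X[, j] <- pmin(pmax(X[, j], bounds[j, 1]), bounds[j, 2])
  }
  X
}

#' Discoverer position update
#'
#' When the alarm value R2 is below the safety threshold ST the environment
#' is safe and discoverer i shrinks its position by `exp(-i / (alpha * T))`
#' per dimension, widening the multiplicative search; otherwise danger has
#' been detected and each discoverer moves near its current position by a
#' normal perturbation. Results are clamped to the bounds.
#'
#' @param X Matrix of discoverer positions, rows ordered by fitness rank
#'   (row r is sparrow rank r).
#' @param cfg An [ssa_config()].
#' @param R2 Alarm value in `[0, 1]`.
#' @param alpha Random scaling draw in (0, 1]; one uniform draw per row when
#'   `NULL`. Exposed for deterministic verification.
#' @param noise Normal perturbation matrix (the Gamma * Z term); drawn
#'   internally when `NULL`. Exposed for deterministic verification.
#' @return Updated position matrix.
#' @export
ssa_step_discoverers <- function(X, cfg, R2, alpha = NULL, noise = NULL) {
  stopifnot(R2 >= 0, R2 <= 1)
  nd <- nrow(X)
  if (nd == 0) return(X)
  if (R2 < cfg$safety_threshold) {
    if (is.null(alpha)) alpha <- stats::runif(nd, min = 1e-12, max = 1)
    alpha <- rep_len(alpha, nd)
    scal <- exp(-(seq_len(nd)) / (alpha * cfg$max_iter))
    X <- X * scal
  } else {
    if (is.null(noise)) {
      noise <- matrix(stats::rnorm(nd * ncol(X)), nd, ncol(X))
    }
    X <- X + noise
  }
  clamp_bounds(X, cfg$bounds)
}

#' Follower position update
#'
#' Followers with rank i > n/2 are starving and scatter around the worst
#' position kernel `Gamma * exp(X_w - X_i)` per dimension; the rest move to
#' the best discoverer position X_p with the `|X_i - X_p| * A+ * Z`
#' correction, where A is a random row vector of +/-1 and A+ = A^T / d.
#' Results are clamped to the bounds.
#'
#' @param X Matrix of follower positions.
#' @param cfg An [ssa_config()].
#' @param x_best Best discoverer position X_p (length-d vector).
#' @param x_worst Worst position X_w in the population.
#' @param ranks Integer global fitness ranks of the follower rows.
#' @param gamma Normal draws (one per starving row); internal when `NULL`.
#' @param A Matrix of +/-1 entries (rows match X); internal when `NULL`.
#' @return Updated position matrix.
#' @export
ssa_step_followers <- function(X, cfg, x_best, x_worst, ranks,
                               gamma = NULL, A = NULL) {
  nf <- nrow(X)
  if (nf == 0) return(X)
  d <- ncol(X)
  n <- cfg$n_sparrows
  starving <- ranks > n / 2
  if (any(starving)) {
    if (is.null(gamma)) gamma <- stats::rnorm(sum(starving))
    rows <- which(starving)
    for (k in seq_along(rows)) {
      i <- rows[k]
      X[i, ] <- gamma[k] * exp(x_worst - X[i, ])
    }
  }
  if (any(!starving)) {
    if (is.null(A)) {
      A <- matrix(sample(c(-1, 1), sum(!starving) * d, replace = TRUE),
                  ncol = d)
    }
    rows <- which(!starving)
    for (k in seq_along(rows)) {
      i <- rows[k]
      # |X_i - X_p| A^T (A A^T)^{-1} 1 collapses to a scalar step since
      # A A^T = d for a +/-1 row vector
      step <- sum(abs(X[i, ] - x_best) * A[k, ]) / d
      X[i, ] <- x_best + step
    }
  }
  clamp_bounds(X, cfg$bounds)
}

#' Alerter position update
#'
#' An alerter already at the global best moves relative to the worst
#' position by `K * (X_i - X_w) / (|f_i - f_w| + delta)` (delta keeps the
#' step finite when fitnesses tie); all other alerters jump toward the best
#' via `X_b + beta * (X_i - X_b)`. Results are clamped to the bounds.
#'
#' @param X Matrix of alerter positions.
#' @param cfg An [ssa_config()].
#' @param x_best Current global best position X_b.
#' @param x_worst Current global worst position X_w.
#' @param f Fitness values of the alerter rows.
#' @param f_best,f_worst Global best and worst fitness values.
#' @param beta Step-control draws (standard normal); internal when `NULL`.
#' @param K Direction draws in `[-1, 1]`; internal when `NULL`.
#' @return Updated position matrix.
#' @export
ssa_step_alerters <- function(X, cfg, x_best, x_worst, f, f_best, f_worst,
                              beta = NULL, K = NULL) {
  na <- nrow(X)
  if (na == 0) return(X)
  if (is.null(beta)) beta <- stats::rnorm(na)
  if (is.null(K)) K <- stats::runif(na, -1, 1)
  beta <- rep_len(beta, na); K <- rep_len(K, na)
  for (i in seq_len(na)) {
    if (f[i] != f_best) {
      X[i, ] <- x_best + beta[i] * (X[i, ] - x_best)
    } else {
      X[i, ] <- X[i, ] + K[i] * (X[i, ] - x_worst) /
        (abs(f[i] - f_worst) + cfg$delta)
    }
  }
  clamp_bounds(X, cfg$bounds)
}

#' Minimize a box-constrained objective with the sparrow search algorithm
#'
#' Initializes a uniform population inside the bounds, then iterates
#' discoverer, follower and alerter updates for `max_iter` generations,
#' keeping an elitist incumbent (the best position ever evaluated). Fully
#' reproducible under the config seed.
#'
#' @param fitness Function mapping a length-d position to a finite scalar
#'   (minimized).
#' @param cfg An [ssa_config()].
#' @return A list with `best_position`, `best_fitness`, `trace` (best-so-far
#'   fitness per iteration, non-increasing) and `n_evaluations`.
#' @examples
#' cfg <- ssa_config(2, c(-5, 5), n_sparrows = 10, max_iter = 20, seed = 7)
#' ssa_optimize(function(x) sum(x^2), cfg)$best_fitness
#' @export
ssa_optimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "ssa_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sparrows; d <- cfg$dimensions
  eval_fit <- function(X) {
    f <- apply(X, 1, fitness)
    if (any(!is.finite(f))) {
      bad <- which(!is.finite(f))[1]
      stop("non-finite fitness at position (",
           paste(signif(X[bad, ], 4), collapse = ", "), ")")
    }
    f
  }
  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2, cfg$bounds[, 2] - cfg$bounds[, 1], "*"),
             2, cfg$bounds[, 1], "+")
  f <- eval_fit(X)
  n_eval <- n
  best_i <- which.min(f)
  inc_pos <- X[best_i, ]; inc_fit <- f[best_i]
  trace <- numeric(cfg$max_iter)
  nd <- max(1L, round(cfg$discoverer_fraction * n))
  na <- max(1L, round(cfg$alerter_fraction * n))

  for (t in seq_len(cfg$max_iter)) {
    ord <- order(f)
    X <- X[ord, , drop = FALSE]; f <- f[ord]
    x_best <- X[1, ]; x_worst <- X[n, ]
    R2 <- stats::runif(1)

    X[1:nd, ] <- ssa_step_discoverers(X[1:nd, , drop = FALSE], cfg, R2)
    x_p <- X[1, ]  # best discoverer after its move
    if (nd < n) {
      rows <- (nd + 1L):n
      X[rows, ] <- ssa_step_followers(X[rows, , drop = FALSE], cfg,
                                      x_best = x_p, x_worst = x_worst,
                                      ranks = rows)
    }
    f <- eval_fit(X); n_eval <- n_eval + n

    al <- sample.int(n, na)
    fb <- min(f); fw <- max(f)
    X[al, ] <- ssa_step_alerters(X[al, , drop = FALSE], cfg,
                                 x_best = X[which.min(f), ],
                                 x_worst = X[which.max(f), ],
                                 f = f[al], f_best = fb, f_worst = fw)
    f[al] <- eval_fit(X[al, , drop = FALSE]); n_eval <- n_eval + na

    it_best <- which.min(f)
    if (f[it_best] < inc_fit) {
      inc_fit <- f[it_best]; inc_pos <- X[it_best, ]
    }
    trace[t] <- inc_fit
  }
  list(best_position = inc_pos, best_fitness = inc_fit, trace = trace,
       n_evaluations = n_eval)
}

#' Uniform random search baseline at a matched evaluation budget
#'
#' @param fitness Objective (minimized).
#' @param cfg An [ssa_config()]; the budget is taken as the number of
#'   evaluations an SSA run with this config performs.
#' @param n_evaluations Override for the evaluation budget.
#' @return A list with `best_position` and `best_fitness`.
#' @export
random_search <- function(fitness, cfg, n_evaluations = NULL) {
  set.seed(cfg$seed)
  if (is.null(n_evaluations)) {
    na <- max(1L, round(cfg$alerter_fraction * cfg$n_sparrows))
    n_evaluations <- cfg$n_sparrows * (1L + cfg$max_iter) +
      na * cfg$max_iter
  }
  d <- cfg$dimensions
  X <- matrix(stats::runif(n_evaluations * d), n_evaluations, d)
  X <- sweep(sweep(X, 2, cfg$bounds[, 2] - cfg$bounds[, 1], "*"),
             2, cfg$bounds[, 1], "+")
  f <- apply(X, 1, fitness)
  best <- which.min(f)
  list(best_position = X[best, ], best_fitness = f[best])
}
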