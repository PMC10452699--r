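#' @importFrom splines splineDesign
NULL

# Full knot vector for `n_basis` B-splines of order `ord` on the range of
# `x`: boundary knots replicated `ord` times, interior knots at equally
# spaced quantiles of the evaluation grid.
spline_knots <- function(x, n_basis, ord = 4L) {
  stopifnot(n_basis >= ord)
  n_interior <- n_basis - ord
  rng <- range(x)
  interior <- if (n_interior > 0) {
    stats::quantile(x, probs = seq(0, 1, length.out = n_interior + 2)[
      -c(1, n_interior + 2)], names = FALSE, type = 7)
  } else numeric(0)
  c(rep(rng[1], ord), interior, rep(rng[2], ord))
}

# Exact Gram matrix of second derivatives: R[k, l] = integral of
# B_k''(t) B_l''(t) dt. For cubic splines the integrand is piecewise
# quadratic, so 3-point Gauss-Legendre per knot span is exact.
roughness_matrix <- function(knots, n_basis, ord = 4L) {
  spans <- unique(knots)
  R <- matrix(0, n_basis, n_basis)
  # 3-point Gauss-Legendre nodes/weights on [-1, 1]
  gl_x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gl_w <- c(5 / 9, 8 / 9, 5 / 9)
  for (i in seq_len(length(spans) - 1)) {
    a <- spans[i]; b <- spans[i + 1]
    if (b <= a) next
    t_eval <- (b - a) / 2 * gl_x + (a + b) / 2
    B2 <- splines::splineDesign(knots, t_eval, ord = ord,
                                derivs = rep(2L, length(t_eval)))
    for (q in seq_along(t_eval)) {
      R <- R + (b - a) / 2 * gl_w[q] * tcrossprod(B2[q, ])
    }
  }
  (R + t(R)) / 2
}

#' Fit a penalized cubic B-spline to a metric-versus-threshold curve
#'
#' Minimizes `sum((y - B c)^2) + lambda * integral(f''(t)^2 dt)` over spline
#' coefficients c, where B is the cubic B-spline basis evaluated at the grid
#' and the roughness penalty is the integrated squared second derivative of
#' the fitted curve (the standard functional-data-analysis smoother). The
#' system is solved in closed form; `penalty = "gcv"` selects lambda by
#' generalized cross-validation over a logarithmic ladder.
#'
#' @param grid Strictly increasing threshold values (or a
#'   [threshold_grid()]).
#' @param y Metric values at the grid points.
#' @param n_basis Number of basis functions (>= 4; at most `length(grid)`
#'   when `penalty = 0`).
#' @param penalty Non-negative smoothing parameter lambda, or `"gcv"`.
#' @param gcv_ladder Candidate lambdas used when `penalty = "gcv"`.
#' @return An object of class `spline_fit` with coefficients, knots, the
#'   chosen lambda, fitted values, the roughness Gram matrix and the fit
#'   domain.
#' @examples
#' g <- threshold_grid()
#' f <- fit_penalized_spline(g$values, g$values^2, n_basis = 10, penalty = 1e-6)
#' @export
fit_penalized_spline <- function(grid, y, n_basis = 10L, penalty = "gcv",
                                 gcv_ladder = 10^seq(-6, 2, length.out = 17)) {
  if (inherits(grid, "threshold_grid")) grid <- grid$values
  stopifnot(length(grid) == length(y), length(grid) >= 2,
            all(diff(grid) > 0), all(is.finite(y)))
  ord <- 4L
  n_basis <- as.integer(n_basis)
  if (n_basis < ord) stop("n_basis must be at least ", ord)
  knots <- spline_knots(grid, n_basis, ord)
  B <- splines::splineDesign(knots, grid, ord = ord)
  R <- roughness_matrix(knots, n_basis, ord)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  n <- length(y)

  solve_for <- function(lam) {
    Mreg <- BtB + lam * R
    ok <- TRUE
    ch <- tryCatch(chol(Mreg), error = function(e) { ok <<- FALSE; NULL })
    if (!ok) return(NULL)
    coef <- backsolve(ch, forwardsolve(t(ch), Bty))
    fitted <- drop(B %*% coef)
    # effective degrees of freedom = trace of the hat matrix
    edf <- sum(diag(B %*% chol2inv(ch) %*% t(B)))
    list(coef = drop(coef), fitted = fitted, edf = edf,
         rss = sum((y - fitted)^2))
  }

  if (identical(penalty, "gcv")) {
    fits <- lapply(gcv_ladder, solve_for)
    gcv <- vapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      if (is.null(f)) return(Inf)
      denom <- max(n - f$edf, 1e-8)
      n * f$rss / denom^2
    }, numeric(1))
    best <- which.min(gcv)
    lambda <- gcv_ladder[best]
    sol <- fits[[best]]
  } else {
    lambda <- as.numeric(penalty)
    if (lambda < 0) stop("penalty must be non-negative")
    if (lambda == 0 && n_basis > n) {
      stop("unpenalized fit with n_basis = ", n_basis, " > ", n,
           " data points is singular; raise the penalty or lower n_basis")
    }
    sol <- solve_for(lambda)
    if (is.null(sol)) {
      stop("normal equations are singular at lambda = ", lambda,
           "; raise the penalty or lower n_basis")
    }
  }
  structure(list(basis_order = ord, n_basis = n_basis, coefficients = sol$coef,
                 penalty = lambda, knots = knots,
                 fit_domain = range(grid), fitted = sol$fitted,
                 rss = sol$rss, edf = sol$edf, roughness_gram = R),
            class = "spline_fit")
}

#' Evaluate a fitted spline curve
#' @param fit A `spline_fit`.
#' @param t Evaluation points inside the fit domain.
#' @param deriv Derivative order (0 = the curve itself).
#' @return Numeric vector of values.
#' @export
eval_spline <- function(fit, t, deriv = 0L) {
  stopifnot(inherits(fit, "spline_fit"))
  if (any(t < fit$fit_domain[1] - 1e-12 | t > fit$fit_domain[2] + 1e-12)) {
    stop("evaluation point(s) outside the fit domain [",
         fit$fit_domain[1], ", ", fit$fit_domain[2], "]")
  }
  t <- pmin(pmax(t, fit$fit_domain[1]), fit$fit_domain[2])
  B <- splines::splineDesign(fit$knots, t, ord = fit$basis_order,
                             derivs = rep(as.integer(deriv), length(t)))
  drop(B %*% fit$coefficients)
}

#' Integrated squared second derivative of a fitted curve
#' @param fit A `spline_fit`.
#' @return The roughness functional value (>= 0).
#' @export
spline_roughness <- function(fit) {
  drop(crossprod(fit$coefficients, fit$roughness_gram %*% fit$coefficients))
}

#' First-derivative (MTD) curve of a fitted spline
#'
#' Evaluates the first derivative of the fitted metric-versus-threshold
#' curve at each grid value; this sampled derivative is the multi-threshold
#' derivative feature vector for one metric of one subject.
#'
#' @param fit A `spline_fit`.
#' @param grid Evaluation thresholds (or a [threshold_grid()]), inside the
#'   fit domain.
#' @param subject_id,metric Identifiers carried on the returned feature.
#' @return An object of class `mtd_feature` with fields `subject_id`,
#'   `metric`, `values` and `grid`.
#' @export
derivative_curve <- function(fit, grid, subject_id = NA_character_,
                             metric = NA_character_) {
  if (inherits(grid, "threshold_grid")) grid <- grid$values
  structure(list(subject_id = subject_id, metric = metric,
                 values = eval_spline(fit, grid, deriv = 1L), grid = grid),
            class = "mtd_feature")
}
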