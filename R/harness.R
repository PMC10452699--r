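#' Build dynamic networks and metric curves for every cohort subject
#'
#' Convenience wrapper running network construction and threshold
#' filtration across a cohort.
#'
#' @param cohort An `mtd_cohort`.
#' @param L,s Sliding-window length and step.
#' @param grid A [threshold_grid()].
#' @param apply_fisher Apply the Fisher R-Z transform.
#' @return A list with `networks` (per-subject `dynamic_network`s),
#'   `curves` (per-subject `metric_curve_set`s), `labels` and the inputs
#'   used.
#' @export
cohort_curves <- function(cohort, L = 85L, s = 3L, grid = threshold_grid(),
                          apply_fisher = TRUE) {
  stopifnot(inherits(cohort, "mtd_cohort"))
  M <- nrow(cohort$subjects[[1]]$data)
  scheme <- make_window_scheme(M, L, s)
  networks <- lapply(cohort$subjects, build_dbfn, scheme = scheme,
                     apply_fisher = apply_fisher)
  curves <- lapply(networks, metric_curves, grid = grid)
  list(networks = networks, curves = curves, labels = cohort_labels(cohort),
       scheme = scheme, grid = grid)
}

#' Area-under-curve features of the metric curves
#'
#' Trapezoidal integral of each metric-versus-threshold curve over the
#' grid: one scalar per metric per subject (the classical multi-threshold
#' summary the derivative features are compared against).
#'
#' @param curve_set A `metric_curve_set`.
#' @return Named numeric vector (cc, Eglobal, Elocal, Lp).
#' @export
area_features <- function(curve_set) {
  vapply(metric_names, function(m) {
    pracma::trapz(curve_set$thresholds, curve_set$curves[, m])
  }, numeric(1))
}

#' Traditional single-threshold topological features
#'
#' Window-mean cc, Eglobal, Elocal and Lp of the binary networks at one
#' fixed threshold.
#'
#' @param net A `dynamic_network`.
#' @param pr The single threshold.
#' @param use_absolute Passed to [binarize()].
#' @return Named numeric vector (cc, Eglobal, Elocal, Lp).
#' @export
traditional_features <- function(net, pr, use_absolute = TRUE) {
  vals <- vapply(net$windows, function(W) {
    graph_metrics(binarize(W, pr, use_absolute))
  }, numeric(4))
  rowMeans(vals)
}

#' Edge-connectivity features
#'
#' Vectorized upper triangle (i < j, column-major order) of the
#' window-mean weighted connectivity matrix: P(P-1)/2 values per subject.
#'
#' @param net A `dynamic_network`.
#' @return Numeric vector of length P(P-1)/2.
#' @export
edge_features <- function(net) {
  W <- mean_network(net)
  W[upper.tri(W)]
}

#' Assemble the feature matrix for one recipe
#'
#' Recipes: `"mtd_fused"` (concatenated derivative curves of the four
#' metrics), `"mtd_cc"` / `"mtd_Eglobal"` / `"mtd_Elocal"` / `"mtd_Lp"`
#' (single-metric derivative curves), `"area"` (four trapezoidal areas),
#' `"traditional"` (four metrics at one threshold, midpoint of the grid by
#' default) and `"edges"` (window-mean edge weights).
#'
#' @param prep Output of [cohort_curves()].
#' @param recipe Recipe name.
#' @param n_basis,penalty Spline settings for the MTD recipes.
#' @param traditional_pr Threshold for the `"traditional"` recipe; defaults
#'   to the midpoint of the grid range.
#' @return Subjects x features numeric matrix.
#' @export
recipe_features <- function(prep, recipe = "mtd_fused", n_basis = 10L,
                            penalty = "gcv", traditional_pr = NULL) {
  known <- c("mtd_fused", paste0("mtd_", metric_names), "area",
             "traditional", "edges")
  if (!recipe %in% known) {
    stop("unknown recipe '", recipe, "'; expected one of ",
         paste(known, collapse = ", "))
  }
  if (startsWith(recipe, "mtd")) {
    mtd <- extract_mtd(prep$curves, n_basis = n_basis, penalty = penalty)
    metric <- if (recipe == "mtd_fused") "fused" else sub("^mtd_", "", recipe)
    return(mtd_feature_matrix(mtd, metric = metric))
  }
  if (recipe == "area") {
    X <- t(vapply(prep$curves, area_features, numeric(4)))
    colnames(X) <- paste0("area_", metric_names)
    return(X)
  }
  if (recipe == "traditional") {
    if (is.null(traditional_pr)) {
      traditional_pr <- mean(range(prep$grid$values))
    }
    X <- t(vapply(prep$networks, traditional_features, numeric(4),
                  pr = traditional_pr))
    colnames(X) <- paste0("trad_", metric_names)
    return(X)
  }
  X <- t(vapply(prep$networks, edge_features,
                numeric(length(edge_features(prep$networks[[1]])))))
  colnames(X) <- paste0("edge_", seq_len(ncol(X)))
  X
}

#' Compare feature recipes under paired cross-validation
#'
#' Runs the full classification pipeline once per recipe on one cohort,
#' with identical fold assignments across recipes (paired comparison), and
#' tabulates ACC/SEN/SPE/AUC per recipe.
#'
#' @param cohort An `mtd_cohort`.
#' @param recipes Character vector of recipe names (see
#'   [recipe_features()]).
#' @param L,s,grid Pipeline settings passed to [cohort_curves()].
#' @param k,repeats,seed,svm_tuning Cross-validation settings (see
#'   [cross_validate()]).
#' @param n_basis,penalty Spline settings for the MTD recipes.
#' @return A list with `table` (one row per recipe: mean and sd of each
#'   metric), `reports` (full `classification_report` per recipe) and
#'   `fold_assignments` shared by all recipes.
#' @export
run_comparison <- function(cohort,
                           recipes = c("mtd_fused", "mtd_cc", "mtd_Eglobal",
                                       "mtd_Elocal", "mtd_Lp", "area",
                                       "traditional", "edges"),
                           L = 85L, s = 3L, grid = threshold_grid(),
                           k = 10L, repeats = 1L, seed = 1L,
                           svm_tuning = list(inner_k = 3L, n_sparrows = 8L,
                                             max_iter = 8L),
                           n_basis = 10L, penalty = "gcv") {
  prep <- cohort_curves(cohort, L = L, s = s, grid = grid)
  y <- prep$labels
  folds <- lapply(seq_len(repeats), function(r) {
    make_folds(y, k = k, seed = (as.integer(seed) + 104729L * r) %% 2147483647L)
  })
  reports <- list()
  for (rc in recipes) {
    X <- tryCatch(recipe_features(prep, rc, n_basis = n_basis,
                                  penalty = penalty),
                  error = function(e) stop("recipe ", rc, ": ",
                                           conditionMessage(e)))
    reports[[rc]] <- cross_validate(X, y, k = k, repeats = repeats,
                                    seed = seed, svm_tuning = svm_tuning,
                                    folds = folds)
  }
  tab <- do.call(rbind, lapply(names(reports), function(rc) {
    a <- reports[[rc]]$aggregate
    data.frame(recipe = rc,
               ACC = a["mean", "ACC"], ACC_sd = a["sd", "ACC"],
               SEN = a["mean", "SEN"], SEN_sd = a["sd", "SEN"],
               SPE = a["mean", "SPE"], SPE_sd = a["sd", "SPE"],
               AUC = a["mean", "AUC"], AUC_sd = a["sd", "AUC"])
  }))
  list(table = tab, reports = reports, fold_assignments = folds)
}

#' Sweep window length, step size and threshold range
#'
#' Re-runs the full pipeline per configuration and collects aggregate
#' metrics in a long-format table. Window configurations with `L > M` are
#' skipped with a warning. By default only the best step per window length
#' is reported; `best_s_only = FALSE` keeps the full (L, s) grid.
#'
#' @param cohort An `mtd_cohort`.
#' @param L_values,s_values Candidate window lengths and steps.
#' @param threshold_ranges List of `c(low, high)` pairs for the grid (step
#'   fixed by `grid_step`); `NULL` sweeps windows only, at the default
#'   grid.
#' @param grid_step Threshold increment.
#' @param recipe Feature recipe evaluated per configuration.
#' @param k,repeats,seed,svm_tuning Cross-validation settings.
#' @param best_s_only Report only the best step per window length.
#' @return Data frame keyed by (L, s, thr_low, thr_high) with mean and sd
#'   ACC/SEN/SPE/AUC.
#' @export
parameter_sweep <- function(cohort, L_values = c(85L), s_values = c(3L),
                            threshold_ranges = NULL, grid_step = 0.01,
                            recipe = "mtd_fused", k = 10L, repeats = 1L,
                            seed = 1L,
                            svm_tuning = list(inner_k = 3L, n_sparrows = 8L,
                                              max_iter = 8L),
                            best_s_only = TRUE) {
  M <- nrow(cohort$subjects[[1]]$data)
  if (is.null(threshold_ranges)) threshold_ranges <- list(c(0.01, 0.35))
  rows <- list()
  for (L in L_values) {
    if (L > M) {
      warning("skipping L = ", L, " > M = ", M)
      next
    }
    for (s in s_values) {
      for (tr in threshold_ranges) {
        grid <- threshold_grid(tr[1], tr[2], grid_step)
        cmp <- run_comparison(cohort, recipes = recipe, L = L, s = s,
                              grid = grid, k = k, repeats = repeats,
                              seed = seed, svm_tuning = svm_tuning)
        row <- cmp$table
        row$recipe <- NULL
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(L = L, s = s, thr_low = tr[1], thr_high = tr[2]), row)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (best_s_only && length(unique(out$s)) > 1) {
    keep <- unlist(lapply(split(seq_len(nrow(out)),
                                list(out$L, out$thr_low, out$thr_high),
                                drop = TRUE),
                          function(ii) ii[which.max(out$ACC[ii])]))
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
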