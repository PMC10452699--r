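#' Extract multi-threshold derivative features for a cohort
#'
#' For every subject and every metric the metric-versus-threshold curve is
#' smoothed with a penalized B-spline and differentiated; the derivative
#' sampled on the shared grid is the MTD feature vector for that metric.
#' All subjects must share one threshold grid.
#'
#' @param curve_sets List of `metric_curve_set`s (one per subject) on a
#'   common grid.
#' @param n_basis Basis dimension of the spline fit.
#' @param penalty Smoothing parameter lambda or `"gcv"` (per-curve
#'   generalized cross-validation; label-free, so it cannot leak group
#'   information).
#' @return A list per subject, each holding one `mtd_feature` per metric
#'   (named cc, Eglobal, Elocal, Lp).
#' @export
extract_mtd <- function(curve_sets, n_basis = 10L, penalty = "gcv") {
  stopifnot(length(curve_sets) >= 1)
  g0 <- curve_sets[[1]]$thresholds
  for (cs in curve_sets) {
    if (!isTRUE(all.equal(cs$thresholds, g0))) {
      stop("all subjects must share one threshold grid (subject ",
           cs$subject_id, " differs)")
    }
  }
  lapply(curve_sets, function(cs) {
    feats <- lapply(metric_names, function(m) {
      fit <- tryCatch(
        fit_penalized_spline(cs$thresholds, cs$curves[, m],
                             n_basis = n_basis, penalty = penalty),
        error = function(e) stop("subject ", cs$subject_id, ", metric ", m,
                                 ": ", conditionMessage(e)))
      derivative_curve(fit, cs$thresholds, subject_id = cs$subject_id,
                       metric = m)
    })
    names(feats) <- metric_names
    feats
  })
}

#' Linearly fuse the four MTD features of one subject
#'
#' Concatenates the per-metric derivative vectors in the fixed order
#' cc, Eglobal, Elocal, Lp. The order is part of the contract (downstream
#' feature-weight attribution relies on the block layout), so permuted or
#' incomplete input is rejected.
#'
#' @param features List of exactly four `mtd_feature`s for one subject, in
#'   the order cc, Eglobal, Elocal, Lp.
#' @return An `mtd_feature` with `metric = "fused"` whose length is the sum
#'   of the four input lengths.
#' @export
fuse_features <- function(features) {
  if (length(features) != 4) {
    stop("fusion requires exactly four MTD features (cc, Eglobal, Elocal, Lp); got ",
         length(features))
  }
  mets <- unname(vapply(features, function(f) f$metric, character(1)))
  if (!identical(mets, metric_names)) {
    stop("features must be supplied in the order cc, Eglobal, Elocal, Lp; got ",
         paste(mets, collapse = ", "))
  }
  ids <- unique(vapply(features, function(f) f$subject_id, character(1)))
  if (length(ids) != 1) {
    stop("all features must belong to one subject; got ",
         paste(ids, collapse = ", "))
  }
  structure(list(subject_id = ids, metric = "fused",
                 values = unlist(lapply(features, `[[`, "values"),
                                 use.names = FALSE),
                 grid = unlist(lapply(features, `[[`, "grid"),
                               use.names = FALSE)),
            class = "mtd_feature")
}

#' Assemble a subjects-by-features matrix from extracted MTD features
#'
#' @param mtd List returned by [extract_mtd()].
#' @param metric One of `"cc"`, `"Eglobal"`, `"Elocal"`, `"Lp"` or
#'   `"fused"`.
#' @return Numeric matrix, one row per subject; columns named
#'   `<metric>_t<threshold>`.
#' @export
mtd_feature_matrix <- function(mtd, metric = "fused") {
  rows <- lapply(mtd, function(feats) {
    f <- if (metric == "fused") fuse_features(feats[metric_names])
         else feats[[metric]]
    f$values
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(mtd, function(f) f[[1]]$subject_id, character(1))
  blk <- if (metric == "fused") rep(metric_names, each = ncol(X) / 4)
         else rep(metric, ncol(X))
  grid1 <- mtd[[1]][[1]]$grid
  colnames(X) <- paste0(blk, "_t", formatC(rep(grid1, length.out = ncol(X)),
                                           format = "f", digits = 2))
  X
}

#' Two-sample t-test of a feature between groups
#'
#' Reduces each subject's feature vector to a scalar summary (the mean by
#' default, or the first principal-component score) and runs a two-sided
#' independent-samples t-test between positive and control groups.
#'
#' @param features List of `mtd_feature`s, or a subjects x features matrix.
#' @param labels Character vector of `"positive"` / `"control"` labels.
#' @param summary_fun `"mean"` or `"pc1"`.
#' @return A list with `metric`, `t_statistic`, `p_value` and `group_means`
#'   (mean feature vector per group).
#' @export
group_difference_test <- function(features, labels,
                                  summary_fun = c("mean", "pc1")) {
  summary_fun <- match.arg(summary_fun)
  if (is.list(features) && inherits(features[[1]], "mtd_feature")) {
    metric <- features[[1]]$metric
    X <- do.call(rbind, lapply(features, `[[`, "values"))
  } else {
    metric <- "matrix"
    X <- as.matrix(features)
  }
  stopifnot(nrow(X) == length(labels))
  pos <- labels == "positive"; ctl <- labels == "control"
  if (sum(pos) < 2 || sum(ctl) < 2) {
    stop("group_difference_test needs at least 2 subjects per group")
  }
  s <- if (summary_fun == "mean") rowMeans(X)
       else stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1]
  if (stats::sd(s[pos]) == 0 && stats::sd(s[ctl]) == 0 &&
      mean(s[pos]) == mean(s[ctl])) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(s[pos], s[ctl], var.equal = FALSE)
  }
  list(metric = metric, t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       group_means = list(positive = colMeans(X[pos, , drop = FALSE]),
                          control = colMeans(X[ctl, , drop = FALSE])))
}

#' Write a subjects-by-features table with a hyperparameter manifest
#'
#' @param X Feature matrix from [mtd_feature_matrix()].
#' @param path Output path for the tab-separated table (header kept).
#' @param hyper Named list of spline hyperparameters actually used; written
#'   alongside as `<path>.params` in `key = value` form.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(X, path, hyper = list()) {
  utils::write.table(data.frame(subject_id = rownames(X), X,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(hyper)) {
    writeLines(paste(names(hyper), unlist(hyper), sep = " = "),
               paste0(path, ".params"))
  }
  invisible(path)
}
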