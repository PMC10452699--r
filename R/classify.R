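#' Stratified fold assignment
#'
#' Assigns subjects to k folds so that both classes appear in every fold
#' (round-robin within each shuffled class). Rejected when a class has
#' fewer members than folds, since no stratification could then place both
#' classes in every fold.
#'
#' @param y Character labels (`"positive"` / `"control"`).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  classes <- unique(y)
  if (min(table(y)) < k) {
    stop("cannot stratify ", k, " folds: smallest class has only ",
         min(table(y)), " subjects")
  }
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cl in classes) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' L1-regularized (lasso) feature selection
#'
#' Fits a binomial lasso path on pre-standardized features and returns the
#' support at the path point chosen by internal cross-validation. Constant
#' columns are dropped with a warning before fitting; an empty support at
#' the chosen regularization is reported as such rather than failing.
#'
#' @param X Subjects x features matrix, standardized per feature on the
#'   training portion.
#' @param y Character labels (`"positive"` / `"control"`), >= 2 per class.
#' @param seed Seed fixing the internal fold assignment.
#' @param nfolds Internal folds for the path choice.
#' @return A list with `indices` (columns of `X` with nonzero coefficient),
#'   `coefficients` (matching values), `lambda` and `dropped` (constant
#'   columns removed).
#' @export
lasso_select <- function(X, y, seed = 1L, nfolds = 5L) {
  stopifnot(nrow(X) == length(y), all(table(y) >= 2))
  sds <- apply(X, 2, stats::sd)
  dropped <- which(sds == 0)
  if (length(dropped)) {
    warning("dropping ", length(dropped), " constant feature column(s)")
    X <- X[, -dropped, drop = FALSE]
  }
  kept <- setdiff(seq_len(length(sds)), dropped)
  yf <- factor(y, levels = c("control", "positive"))
  nf <- min(nfolds, min(table(yf)))
  foldid <- make_folds(as.character(yf), k = nf, seed = seed)
  cvfit <- glmnet::cv.glmnet(X, yf, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]  # drop intercept
  nz <- which(beta != 0)
  list(indices = kept[nz], coefficients = beta[nz],
       lambda = cvfit$lambda.min, dropped = dropped)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney estimate: the probability that a random positive subject
#' scores above a random negative subject, with tied scores sharing their
#' average rank.
#'
#' @param scores Continuous decision scores (higher = more positive).
#' @param y Character labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  pos <- y == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(TP, FP, TN, FN) {
  c(ACC = (TP + TN) / (TP + FP + TN + FN),
    SEN = TP / (TP + FN),
    SPE = TN / (TN + FP))
}

#' Train an RBF-kernel SVM and evaluate it on held-out data
#'
#' Fits a radial-kernel maximum-margin classifier with cost `C` and kernel
#' width `Gamma` on the training portion and returns held-out confusion
#' counts plus continuous decision scores (oriented so that higher means
#' more positive), which feed the AUC.
#'
#' @param X_train,y_train Training features and labels (both classes must
#'   be present).
#' @param X_test,y_test Held-out features and labels.
#' @param C Penalty coefficient (> 0).
#' @param Gamma RBF kernel width (> 0).
#' @return A list with `TP`, `FP`, `TN`, `FN`, `ACC`, `SEN`, `SPE`, `AUC`,
#'   `scores` and `predicted`.
#' @export
train_eval_svm <- function(X_train, y_train, X_test, y_test, C, Gamma) {
  stopifnot(C > 0, Gamma > 0)
  if (length(unique(y_train)) < 2) {
    stop("single-class training fold (", length(y_train), " subjects, all ",
         unique(y_train), ")")
  }
  yf <- factor(y_train, levels = c("control", "positive"))
  fit <- e1071::svm(x = X_train, y = yf, kernel = "radial", cost = C,
                    gamma = Gamma, scale = FALSE)
  pred <- stats::predict(fit, X_test, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient scores so larger = more positive, whatever e1071's level order
  if (grepl("^control/", colnames(attr(pred, "decision.values"))[1])) {
    dv <- -dv
  }
  pred <- as.character(pred)
  TP <- sum(pred == "positive" & y_test == "positive")
  FP <- sum(pred == "positive" & y_test == "control")
  TN <- sum(pred == "control" & y_test == "control")
  FN <- sum(pred == "control" & y_test == "positive")
  m <- confusion_metrics(TP, FP, TN, FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       ACC = m[["ACC"]], SEN = m[["SEN"]], SPE = m[["SPE"]],
       AUC = auc_score(dv, y_test), scores = dv, predicted = pred)
}

# Inner cross-validated accuracy for one (C, Gamma); the SSA fitness is
# 1 - this value.
inner_cv_accuracy <- function(X, y, C, Gamma, folds) {
  acc <- 0; ntot <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    res <- train_eval_svm(X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], y[!tr], C, Gamma)
    acc <- acc + (res$TP + res$TN)
    ntot <- ntot + sum(!tr)
  }
  acc / ntot
}

#' Tune SVM hyperparameters with the sparrow search algorithm
#'
#' Searches (C, Gamma) in log10 space over `C in [1e-2, 1e3]`,
#' `Gamma in [1e-4, 1e1]`, minimizing one minus the inner cross-validated
#' accuracy on the supplied (training) data only.
#'
#' @param X,y Training features and labels.
#' @param seed Seed for the SSA run and the inner fold split.
#' @param inner_k Inner folds for the fitness (capped by class sizes).
#' @param n_sparrows,max_iter SSA budget for the tuning run.
#' @param bounds_log10 2 x 2 matrix of log10 bounds for (C, Gamma).
#' @return A list with `C`, `Gamma`, `fitness` (1 - inner accuracy) and the
#'   SSA `trace`.
#' @export
tune_svm_ssa <- function(X, y, seed = 1L, inner_k = 3L, n_sparrows = 8L,
                         max_iter = 8L,
                         bounds_log10 = rbind(c(-2, 3), c(-4, 1))) {
  inner_k <- min(inner_k, min(table(y)))
  folds <- make_folds(y, k = inner_k, seed = seed)
  fitness <- function(pos) {
    1 - inner_cv_accuracy(X, y, C = 10^pos[1], Gamma = 10^pos[2], folds)
  }
  cfg <- ssa_config(2, bounds_log10, n_sparrows = n_sparrows,
                    max_iter = max_iter, seed = seed)
  opt <- ssa_optimize(fitness, cfg)
  list(C = 10^opt$best_position[1], Gamma = 10^opt$best_position[2],
       fitness = opt$best_fitness, trace = opt$trace)
}

fit_fold <- function(X, y, test_idx, seed, svm_tuning) {
  tr_idx <- setdiff(seq_len(nrow(X)), test_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]
  # standardization statistics from the training portion only
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  keep <- which(scl > 0)
  Xtr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  Xte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")

  sel <- suppressWarnings(lasso_select(Xtr, ytr, seed = seed))
  sel_idx <- sel$indices
  if (length(sel_idx) == 0) sel_idx <- seq_along(keep)  # empty support: keep all
  Xtr_s <- Xtr[, sel_idx, drop = FALSE]
  Xte_s <- Xte[, sel_idx, drop = FALSE]

  tuned <- tune_svm_ssa(Xtr_s, ytr, seed = seed,
                        inner_k = svm_tuning$inner_k,
                        n_sparrows = svm_tuning$n_sparrows,
                        max_iter = svm_tuning$max_iter)
  res <- train_eval_svm(Xtr_s, ytr, Xte_s, yte, tuned$C, tuned$Gamma)
  res$artifacts <- list(selected = keep[sel_idx], C = tuned$C,
                        Gamma = tuned$Gamma, center = ctr, scale = scl,
                        lasso_empty = length(sel$indices) == 0)
  res
}

#' Repeated stratified k-fold cross-validation of the SSA-SVM classifier
#'
#' For every fold, standardization, lasso selection and the SSA search for
#' (C, Gamma) are fit on the training portion only; the held-out fold is
#' touched once, for evaluation. Reports fold-wise confusion counts,
#' ACC/SEN/SPE/AUC and the chosen hyperparameters, aggregated as mean and
#' standard deviation over folds x repeats.
#'
#' @param X Subjects x features matrix (raw scale; per-fold standardization
#'   is internal).
#' @param y Character labels (`"positive"` / `"control"`).
#' @param k Folds (default 10).
#' @param repeats Repetitions of the k-fold split.
#' @param seed Master seed; per-repeat and per-fold seeds derive from it.
#' @param svm_tuning List with `inner_k`, `n_sparrows`, `max_iter`
#'   controlling the per-fold SSA tuning budget.
#' @param folds Optional precomputed fold assignment (vector for one
#'   repeat, or a list of length `repeats`); used by the comparison harness
#'   to pair recipes on identical splits.
#' @return An object of class `classification_report`: `folds` data frame
#'   (one row per fold x repeat), `aggregate` (mean and sd per metric),
#'   `fold_details` (per-fold training artifacts) and `fold_assignments`.
#' @export
cross_validate <- function(X, y, k = 10L, repeats = 1L, seed = 1L,
                           svm_tuning = list(inner_k = 3L, n_sparrows = 8L,
                                             max_iter = 8L),
                           folds = NULL) {
  stopifnot(nrow(X) == length(y))
  if (!is.null(folds) && !is.list(folds)) folds <- list(folds)
  rows <- list(); details <- list(); assignments <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- (as.integer(seed) + 104729L * r) %% 2147483647L
    fold_id <- if (!is.null(folds)) folds[[min(r, length(folds))]]
               else make_folds(y, k = k, seed = rep_seed)
    assignments[[r]] <- fold_id
    for (fk in sort(unique(fold_id))) {
      test_idx <- which(fold_id == fk)
      if (length(unique(y[test_idx])) < 2 && length(test_idx) > 1) {
        # tolerated: SEN/SPE of a one-class test fold are NA-safe below
      }
      fold_seed <- (rep_seed + 613L * fk) %% 2147483647L
      res <- fit_fold(X, y, test_idx, seed = fold_seed,
                      svm_tuning = svm_tuning)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = fk, TP = res$TP, FP = res$FP, TN = res$TN,
        FN = res$FN, ACC = res$ACC, SEN = res$SEN, SPE = res$SPE,
        AUC = res$AUC, C = res$artifacts$C, Gamma = res$artifacts$Gamma,
        n_selected = length(res$artifacts$selected))
      details[[length(details) + 1L]] <- res$artifacts
    }
  }
  fold_df <- do.call(rbind, rows)
  agg <- sapply(c("ACC", "SEN", "SPE", "AUC"), function(m) {
    v <- fold_df[[m]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  structure(list(folds = fold_df, aggregate = agg, fold_details = details,
                 fold_assignments = assignments, seed = seed),
            class = "classification_report")
}

#' @exportS3Method base::print
print.classification_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("ACC %.2f%% +/- %.2f | SEN %.2f%% +/- %.2f | SPE %.2f%% +/- %.2f | AUC %.4f +/- %.4f  (%d folds)\n",
              100 * a["mean", "ACC"], 100 * a["sd", "ACC"],
              100 * a["mean", "SEN"], 100 * a["sd", "SEN"],
              100 * a["mean", "SPE"], 100 * a["sd", "SPE"],
              a["mean", "AUC"], a["sd", "AUC"], nrow(x$folds)))
  invisible(x)
}

#' Write a classification report as a delimited table
#'
#' One row per fold x repeat plus an aggregate summary row.
#'
#' @param report A `classification_report`.
#' @param path Output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  df <- report$folds
  agg <- report$aggregate
  summary_row <- df[1, ]
  summary_row[] <- NA
  summary_row$repeat_id <- NA
  for (m in c("ACC", "SEN", "SPE", "AUC")) summary_row[[m]] <- agg["mean", m]
  out <- rbind(cbind(row_type = "fold", df),
               cbind(row_type = "aggregate_mean", summary_row))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Percentage of feature weight carried by each metric block
#'
#' Sums absolute weights within each block of the fused feature layout
#' (cc, Eglobal, Elocal, Lp) and normalizes to percentages summing to 100.
#' All-zero weights leave the percentages undefined and are reported as
#' `NA` with a warning.
#'
#' @param weights Per-feature weights (e.g. lasso coefficients on the fused
#'   vector, zeros for unselected features).
#' @param blocks Character vector mapping each feature to its metric block;
#'   defaults to four equal consecutive blocks.
#' @return Named numeric vector of percentages (cc, Eglobal, Elocal, Lp).
#' @export
feature_weight_percentages <- function(weights, blocks = NULL) {
  if (is.null(blocks)) {
    stopifnot(length(weights) %% 4 == 0)
    blocks <- rep(metric_names, each = length(weights) / 4)
  }
  stopifnot(length(blocks) == length(weights))
  tot <- tapply(abs(weights), factor(blocks, levels = metric_names), sum)
  tot <- stats::setNames(as.vector(tot), metric_names)
  tot[is.na(tot)] <- 0
  s <- sum(tot)
  if (s == 0) {
    warning("all weights are zero; block percentages are undefined")
    return(stats::setNames(rep(NA_real_, 4), metric_names))
  }
  100 * tot / s
}
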