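#' Specify a modular covariance structure for synthetic ROI time series
#'
#' Describes a block (modular) correlation structure over `n_regions` brain
#' regions: region pairs in the same module correlate at `intra_corr`, pairs
#' in different modules at `inter_corr`, and the marginal standard deviation
#' of every region is `noise_sd`. This is the generating model for synthetic
#' cohorts that stand in for patient resting-state fMRI, whose hallmark is a
#' community-structured connectivity matrix.
#'
#' @param n_regions Number of regions P (>= 2).
#' @param n_modules Number of equally sized modules regions are assigned to
#'   (round-robin when P is not a multiple). Ignored when `module_assignment`
#'   is given.
#' @param intra_corr Within-module correlation, in `[0, 1)`.
#' @param inter_corr Between-module correlation, in `[0, 1)`, strictly less
#'   than `intra_corr` unless both are zero.
#' @param noise_sd Marginal standard deviation of each region's signal (> 0).
#' @param module_assignment Optional integer vector of length `n_regions`
#'   giving an explicit region-to-module map.
#' @return An object of class `covariance_spec`.
#' @examples
#' spec <- covariance_spec(20, n_modules = 4, intra_corr = 0.6, inter_corr = 0.1)
#' @export
covariance_spec <- function(n_regions, n_modules = 1, intra_corr = 0.5,
                            inter_corr = 0.0, noise_sd = 1.0,
                            module_assignment = NULL) {
  stopifnot(n_regions >= 2, noise_sd > 0)
  if (!(intra_corr >= 0 && intra_corr < 1)) {
    stop("intra_corr must lie in [0, 1), got ", intra_corr)
  }
  if (!(inter_corr >= 0 && inter_corr < 1)) {
    stop("inter_corr must lie in [0, 1), got ", inter_corr)
  }
  if (inter_corr > intra_corr) {
    stop("inter_corr (", inter_corr, ") must not exceed intra_corr (",
         intra_corr, ")")
  }
  if (is.null(module_assignment)) {
    module_assignment <- rep_len(seq_len(n_modules), n_regions)
    module_assignment <- sort(module_assignment)
  }
  stopifnot(length(module_assignment) == n_regions)
  structure(
    list(n_regions = as.integer(n_regions),
         module_assignment = as.integer(module_assignment),
         intra_corr = intra_corr, inter_corr = inter_corr,
         noise_sd = noise_sd),
    class = "covariance_spec"
  )
}

#' Build the correlation matrix implied by a covariance specification
#'
#' Entry (i, j) equals `intra_corr` when regions i and j share a module and
#' `inter_corr` otherwise, with a unit diagonal. The result is checked for
#' positive definiteness by its smallest eigenvalue; combinations that are
#' not positive definite are rejected.
#'
#' @param spec A [covariance_spec()].
#' @return A P x P positive-definite correlation matrix (unit diagonal).
#' @examples
#' R <- build_covariance(covariance_spec(4, 2, intra_corr = 0.5, inter_corr = 0.1))
#' @export
build_covariance <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  same <- outer(spec$module_assignment, spec$module_assignment, "==")
  R <- ifelse(same, spec$intra_corr, spec$inter_corr)
  diag(R) <- 1
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop("covariance specification is not positive definite ",
         "(smallest eigenvalue ", signif(ev_min, 4), ")")
  }
  R
}

#' Draw one subject's ROI time series from a given covariance
#'
#' Rows are independent draws from a zero-mean multivariate normal with the
#' supplied covariance, i.e. a stationary white-in-time signal whose spatial
#' correlation structure is exactly `cov`. An optional AR(1) coefficient
#' `ar_phi` smooths the series in time while preserving the stationary
#' spatial covariance (innovations are scaled by `sqrt(1 - ar_phi^2)`).
#'
#' @param cov Positive-definite P x P covariance (or correlation) matrix.
#' @param M Number of timepoints (>= 2).
#' @param label Group label, one of `"positive"` or `"control"`.
#' @param seed Integer seed; identical seeds yield identical subjects.
#' @param subject_id Subject identifier string.
#' @param noise_sd Marginal scale applied to the draw (the matrix is treated
#'   as a correlation matrix when this is not 1).
#' @param ar_phi AR(1) temporal smoothing coefficient in `[0, 1)`; 0 (the
#'   default) gives temporally independent rows.
#' @return An object of class `ts_subject` with fields `data` (M x P matrix),
#'   `label` and `subject_id`.
#' @export
sample_subject <- function(cov, M, label = c("control", "positive"),
                           seed = 1L, subject_id = "s1", noise_sd = 1.0,
                           ar_phi = 0.0) {
  label <- match.arg(label)
  if (M < 2) stop("M must be at least 2, got ", M)
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov), ar_phi >= 0, ar_phi < 1)
  set.seed(as.integer(seed))
  X <- MASS::mvrnorm(n = M, mu = rep(0, nrow(cov)), Sigma = cov)
  if (ar_phi > 0) {
    scale_innov <- sqrt(1 - ar_phi^2)
    for (t in 2:M) X[t, ] <- ar_phi * X[t - 1, ] + scale_innov * X[t, ]
  }
  X <- X * noise_sd
  dimnames(X) <- NULL
  structure(list(data = X, label = label, subject_id = subject_id),
            class = "ts_subject")
}

#' Generate a two-group synthetic cohort with a planted connectivity effect
#'
#' Control subjects are drawn from `base_spec`; positive subjects from the
#' same specification with the within-module correlation reduced by `effect`,
#' emulating the weakened integration/segregation seen in cognitively
#' impaired groups. Per-subject seeds are derived deterministically from the
#' cohort seed, so identical seeds reproduce the cohort bit for bit.
#'
#' @param n_pos,n_ctrl Number of positive and control subjects.
#' @param M Timepoints per subject.
#' @param base_spec A [covariance_spec()] describing the control group.
#' @param effect Reduction of `intra_corr` in the positive group (>= 0);
#'   must keep the positive group's intra correlation at or above
#'   `inter_corr`.
#' @param seed Cohort master seed.
#' @param ar_phi AR(1) smoothing passed to [sample_subject()].
#' @return An object of class `mtd_cohort`: list of `ts_subject`s plus
#'   counts and the seed.
#' @examples
#' co <- generate_cohort(5, 5, M = 60,
#'                       base_spec = covariance_spec(10, 2, 0.6, 0.1),
#'                       effect = 0.3, seed = 1)
#' @export
generate_cohort <- function(n_pos, n_ctrl, M, base_spec, effect = 0,
                            seed = 1L, ar_phi = 0.0) {
  stopifnot(inherits(base_spec, "covariance_spec"), n_pos >= 1, n_ctrl >= 1)
  if (effect < 0) stop("effect must be non-negative, got ", effect)
  if (base_spec$intra_corr - effect < base_spec$inter_corr) {
    stop("effect ", effect, " drives intra_corr below inter_corr (",
         base_spec$intra_corr, " - ", effect, " < ", base_spec$inter_corr, ")")
  }
  pos_spec <- base_spec
  pos_spec$intra_corr <- base_spec$intra_corr - effect
  R_ctrl <- build_covariance(base_spec)
  R_pos <- build_covariance(pos_spec)

  n_total <- n_pos + n_ctrl
  labels <- c(rep("positive", n_pos), rep("control", n_ctrl))
  # deterministic per-subject seeds, kept inside the 32-bit integer range
  sub_seeds <- (as.integer(seed) + 7919L * seq_len(n_total)) %% 2147483647L
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    R <- if (labels[i] == "positive") R_pos else R_ctrl
    subjects[[i]] <- sample_subject(
      R, M, label = labels[i], seed = sub_seeds[i],
      subject_id = sprintf("%s_%03d", substr(labels[i], 1, 3), i),
      noise_sd = base_spec$noise_sd, ar_phi = ar_phi
    )
  }
  structure(list(subjects = subjects, n_positive = as.integer(n_pos),
                 n_control = as.integer(n_ctrl), seed = as.integer(seed)),
            class = "mtd_cohort")
}

#' @exportS3Method base::print
print.mtd_cohort <- function(x, ...) {
  M <- nrow(x$subjects[[1]]$data); P <- ncol(x$subjects[[1]]$data)
  cat(sprintf("mtd_cohort: %d positive + %d control subjects, %d x %d series (seed %d)\n",
              x$n_positive, x$n_control, M, P, x$seed))
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort An `mtd_cohort`.
#' @return Character vector of `"positive"` / `"control"` labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) s$label, character(1))
}

#' Write a cohort to delimited text files
#'
#' Each subject is written as a tab-separated M x P matrix without a header,
#' plus a comma-separated manifest (`subject_id`, `path`, `label`).
#'
#' @param cohort An `mtd_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".tsv"))
    utils::write.table(s$data, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    data.frame(subject_id = s$subject_id, path = path, label = s$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to the comma-separated manifest.
#' @return An `mtd_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "path", "label") %in% names(manifest)))
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    X <- as.matrix(utils::read.table(p, sep = "\t"))
    dimnames(X) <- NULL
    if (anyNA(X)) stop("missing values in ", p)
    structure(list(data = X, label = manifest$label[i],
                   subject_id = manifest$subject_id[i]),
              class = "ts_subject")
  })
  labs <- vapply(subjects, function(s) s$label, character(1))
  structure(list(subjects = subjects,
                 n_positive = sum(labs == "positive"),
                 n_control = sum(labs == "control"),
                 seed = NA_integer_),
            class = "mtd_cohort")
}
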