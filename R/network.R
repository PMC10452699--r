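#' Sliding-window scheme for dynamic network construction
#'
#' Divides an M-point series into D = floor((M - L)/s) + 1 overlapping
#' windows of length L advanced by step s. Window d (1-based) covers
#' timepoints (d-1)*s + 1 through (d-1)*s + L, inclusive, so the last window
#' always fits inside the series.
#'
#' @param M Total number of timepoints.
#' @param L Window length (2 <= L <= M).
#' @param s Step size (>= 1).
#' @return An object of class `window_scheme` with fields `M`, `L`, `s`,
#'   `n_windows` and a `starts` vector.
#' @examples
#' make_window_scheme(100, 85, 3)$n_windows  # 6
#' @export
make_window_scheme <- function(M, L, s = 1L) {
  if (L > M) stop("window length L = ", L, " exceeds series length M = ", M)
  stopifnot(L >= 2, s >= 1)
  D <- floor((M - L) / s) + 1
  starts <- (seq_len(D) - 1L) * as.integer(s) + 1L
  structure(list(M = as.integer(M), L = as.integer(L), s = as.integer(s),
                 n_windows = as.integer(D), starts = starts),
            class = "window_scheme")
}

#' Pearson correlation matrix of one window, with zero diagonal
#'
#' Columns are centered and standardized and the correlation matrix is the
#' cross-product of the standardized matrix (the closed-form minimizer of the
#' Frobenius fitting problem). The diagonal is fixed at 0: self-connections
#' carry no information and would be mapped to infinity by the Fisher
#' transform.
#'
#' @param X_window L x P matrix (timepoints by regions).
#' @return P x P symmetric matrix, zero diagonal, off-diagonal in `[-1, 1]`.
#' @export
window_correlation <- function(X_window) {
  stopifnot(is.matrix(X_window), nrow(X_window) >= 2)
  sds <- apply(X_window, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    stop("zero-variance region(s) in window: ", paste(bad, collapse = ", "))
  }
  Z <- scale(X_window, center = TRUE, scale = TRUE)
  R <- crossprod(Z) / (nrow(X_window) - 1)
  R <- (R + t(R)) / 2
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 0
  dimnames(R) <- NULL
  R
}

#' Fisher R-Z variance-stabilizing transform
#'
#' Maps a correlation r to z = (1/2) * log((1 + r) / (1 - r)). Odd and
#' strictly increasing; perfect correlations (|r| >= 1) have no finite image
#' and are rejected.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return Transformed values on the z scale.
#' @examples
#' fisher_z(0.5)  # 0.5493... = log(3)/2
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1; got value(s) with |r| >= 1")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Build a dynamic brain functional network from one subject
#'
#' Slides the window scheme across the subject's time series and computes a
#' weighted correlation network per window; the Fisher R-Z transform is
#' applied elementwise to off-diagonal entries by default to stabilize the
#' variance of the correlation estimates. Diagonals stay 0.
#'
#' @param subject A `ts_subject` (see [sample_subject()]).
#' @param scheme A [make_window_scheme()] consistent with the subject's M.
#' @param apply_fisher Apply the Fisher transform (default `TRUE`).
#' @return An object of class `dynamic_network`: `subject_id`, a list
#'   `windows` of P x P matrices and the `fisher_applied` flag.
#' @export
build_dbfn <- function(subject, scheme, apply_fisher = TRUE) {
  stopifnot(inherits(subject, "ts_subject"), inherits(scheme, "window_scheme"))
  M <- nrow(subject$data)
  if (scheme$M != M) {
    stop("window scheme was built for M = ", scheme$M,
         " but subject has M = ", M)
  }
  windows <- vector("list", scheme$n_windows)
  for (d in seq_len(scheme$n_windows)) {
    idx <- scheme$starts[d]:(scheme$starts[d] + scheme$L - 1L)
    R <- tryCatch(window_correlation(subject$data[idx, , drop = FALSE]),
                  error = function(e) {
                    stop("window ", d, ": ", conditionMessage(e))
                  })
    if (apply_fisher) {
      off <- row(R) != col(R)
      R[off] <- fisher_z(R[off])
    }
    windows[[d]] <- R
  }
  structure(list(subject_id = subject$subject_id, windows = windows,
                 fisher_applied = apply_fisher),
            class = "dynamic_network")
}

#' Window-mean weighted connectivity matrix of a dynamic network
#' @param net A `dynamic_network`.
#' @return P x P matrix, the elementwise mean across windows.
#' @export
mean_network <- function(net) {
  stopifnot(inherits(net, "dynamic_network"))
  Reduce(`+`, net$windows) / length(net$windows)
}

#' Persist a dynamic network as delimited matrices plus an index sidecar
#'
#' One tab-separated matrix file per window and a comma-separated index
#' (`window`, `path`) alongside.
#'
#' @param net A `dynamic_network`.
#' @param dir Output directory.
#' @return Invisibly, the index path.
#' @export
write_dbfn <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(net$windows))
  for (d in seq_along(net$windows)) {
    paths[d] <- file.path(dir, sprintf("%s_w%03d.tsv", net$subject_id, d))
    utils::write.table(net$windows[[d]], paths[d], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  idx <- file.path(dir, paste0(net$subject_id, "_index.csv"))
  utils::write.csv(data.frame(window = seq_along(paths), path = paths),
                   idx, row.names = FALSE)
  invisible(idx)
}
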