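#' Threshold grid for multi-threshold filtration
#'
#' The ordered sequence low, low + step, ... up to `high`, all strictly
#' positive. The default 0.01 to 0.35 in steps of 0.01 (35 thresholds) is the
#' absolute-threshold range at which binary network families are usually most
#' discriminative for functional connectivity.
#'
#' @param low,high Range endpoints (0 < low <= high).
#' @param step Increment (> 0).
#' @return An object of class `threshold_grid` with a `values` vector.
#' @examples
#' length(threshold_grid()$values)  # 35
#' @export
threshold_grid <- function(low = 0.01, high = 0.35, step = 0.01) {
  stopifnot(low > 0, step > 0, high >= low)
  values <- seq(low, high + step / 1e6, by = step)
  values <- values[values <= high + step / 1e6]
  structure(list(low = low, high = high, step = step, values = values),
            class = "threshold_grid")
}

#' Binarize a weighted network at one threshold
#'
#' An edge is kept when `|w_ij| > pr` (default) or, in signed mode, when
#' `w_ij > pr`. Fisher-transformed correlation weights are signed and the
#' absolute-value rule is the dominant convention for binary brain networks.
#'
#' @param weighted Symmetric P x P matrix with zero diagonal.
#' @param pr Threshold (> 0).
#' @param use_absolute Compare `|w|` (default) rather than `w` against `pr`.
#' @return P x P symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize <- function(weighted, pr, use_absolute = TRUE) {
  stopifnot(is.matrix(weighted), nrow(weighted) == ncol(weighted), pr > 0)
  if (!isTRUE(all.equal(weighted, t(weighted), tolerance = 1e-12))) {
    stop("binarize requires a symmetric weight matrix")
  }
  w <- if (use_absolute) abs(weighted) else weighted
  A <- (w > pr) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

as_adj_int <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  storage.mode(A) <- "integer"
  A
}

#' Mean clustering coefficient of a binary graph
#'
#' Average over nodes of C_i = 2 t_i / (k_i (k_i - 1)), where t_i counts
#' triangles through node i and k_i is its degree; nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param A Symmetric 0/1 adjacency matrix, zero diagonal.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(A) {
  if (nrow(A) == 0) return(0)
  .metrics_binary(as_adj_int(A))[["cc"]]
}

#' Characteristic path length over mutually reachable pairs
#'
#' Mean shortest-path length over ordered pairs (i != j) that are reachable
#' from one another; pairs in different components are excluded from the
#' average, and a graph with no reachable pair returns 0.
#'
#' @inheritParams clustering_coefficient
#' @return Value >= 0 (>= 1 whenever some pair is reachable).
#' @export
characteristic_path_length <- function(A) {
  if (nrow(A) < 2) return(0)
  .metrics_binary(as_adj_int(A))[["Lp"]]
}

#' Global efficiency of a binary graph
#'
#' (1 / (P (P - 1))) * sum over ordered pairs of 1 / d_ij, where unreachable
#' pairs contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Value in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  if (nrow(A) < 2) return(0)
  .metrics_binary(as_adj_int(A))[["Eglobal"]]
}

#' Local efficiency of a binary graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours; nodes with fewer than two neighbours contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Value in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  if (nrow(A) == 0) return(0)
  .metrics_binary(as_adj_int(A))[["Elocal"]]
}

metric_names <- c("cc", "Eglobal", "Elocal", "Lp")

#' All four topological properties of one binary graph
#' @inheritParams clustering_coefficient
#' @return Named vector (cc, Eglobal, Elocal, Lp).
#' @export
graph_metrics <- function(A) {
  if (nrow(A) == 0) return(stats::setNames(rep(0, 4), metric_names))
  .metrics_binary(as_adj_int(A))
}

#' Topological-property curves over a threshold grid
#'
#' For every window and threshold the weighted network is binarized and the
#' four properties (cc, Eglobal, Elocal, Lp) are computed. Under the default
#' `"window-mean"` aggregation the across-window average at each threshold is
#' returned, giving one curve per metric per subject; `"per-window"` retains
#' the full window x threshold array.
#'
#' @param net A `dynamic_network`.
#' @param grid A [threshold_grid()].
#' @param aggregation `"window-mean"` (default) or `"per-window"`.
#' @param use_absolute Passed to [binarize()].
#' @return An object of class `metric_curve_set`: `subject_id`, `thresholds`
#'   and a `curves` matrix (thresholds x 4 metrics); under `"per-window"`, a
#'   `per_window` array (window x threshold x metric) is attached as well.
#' @export
metric_curves <- function(net, grid = threshold_grid(),
                          aggregation = c("window-mean", "per-window"),
                          use_absolute = TRUE) {
  stopifnot(inherits(net, "dynamic_network"), inherits(grid, "threshold_grid"),
            length(net$windows) >= 1, length(grid$values) >= 1)
  aggregation <- match.arg(aggregation)
  D <- length(net$windows); Tn <- length(grid$values)
  arr <- array(NA_real_, dim = c(D, Tn, 4),
               dimnames = list(NULL, NULL, metric_names))
  for (d in seq_len(D)) {
    W <- net$windows[[d]]
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12))) {
      stop("window ", d, ": asymmetric weight matrix")
    }
    arr[d, , ] <- .metrics_over_grid(W, grid$values, use_absolute)
  }
  curves <- apply(arr, c(2, 3), mean)
  colnames(curves) <- metric_names
  out <- structure(list(subject_id = net$subject_id,
                        thresholds = grid$values,
                        curves = curves,
                        aggregation = aggregation),
                   class = "metric_curve_set")
  if (aggregation == "per-window") out$per_window <- arr
  out
}

#' Write metric curves as a delimited per-subject table
#'
#' Rows are thresholds and columns the four metrics, tab-separated with a
#' header.
#'
#' @param curve_set A `metric_curve_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_metric_curves <- function(curve_set, path) {
  df <- data.frame(threshold = curve_set$thresholds, curve_set$curves)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long-format cohort table of metric curves
#'
#' @param curve_sets List of `metric_curve_set`s.
#' @return Data frame with columns `subject_id`, `metric`, `threshold`,
#'   `value`.
#' @export
curves_long_table <- function(curve_sets) {
  do.call(rbind, lapply(curve_sets, function(cs) {
    do.call(rbind, lapply(metric_names, function(m) {
      data.frame(subject_id = cs$subject_id, metric = m,
                 threshold = cs$thresholds, value = cs$curves[, m],
                 stringsAsFactors = FALSE)
    }))
  }))
}
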