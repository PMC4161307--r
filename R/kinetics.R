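## Kinetic analysis of per-peak intensity time courses.

#' Construct a time-course matrix
#'
#' @param intensities numeric matrix: peaks (rows) x timepoints (columns),
#'   no missing entries.
#' @param timepoints numeric timepoints (e.g. minutes), strictly increasing;
#'   defaults to numeric column names.
#' @return a `timecourse_matrix` (a numeric matrix with a `timepoints`
#'   attribute).
#' @export
timecourse_matrix <- function(intensities, timepoints = NULL) {
  m <- as.matrix(intensities)
  if (anyNA(m)) {
    cf_stop("time-course matrix must have no missing entries",
            class = "citfoot_validation_error")
  }
  if (is.null(timepoints)) timepoints <- as.numeric(colnames(m))
  timepoints <- as.numeric(timepoints)
  if (anyNA(timepoints) || length(timepoints) != ncol(m) ||
      any(diff(timepoints) <= 0)) {
    cf_stop("timepoints must be strictly increasing and match the columns",
            class = "citfoot_validation_error")
  }
  colnames(m) <- timepoints
  attr(m, "timepoints") <- timepoints
  class(m) <- c("timecourse_matrix", class(matrix()))
  m
}

row_max_normalize <- function(m) {
  mx <- apply(m, 1L, max)
  mx[mx == 0] <- 1  # all-zero rows stay zero
  sweep(m, 1L, mx, "/")
}

#' Cluster peak time courses by kinetic shape
#'
#' Agglomerative clustering with Euclidean distance on per-row
#' max-normalized profiles (so clusters reflect kinetic shape rather than
#' absolute intensity), cut at `k` clusters. The returned row ordering is
#' the dendrogram leaf order, suitable for heatmap display.
#'
#' @param matrix a [timecourse_matrix] (or plain numeric matrix).
#' @param k number of clusters (`2 <= k <= nrow`).
#' @param normalize `"max"` (default) or `"none"`.
#' @param linkage agglomeration method passed to [stats::hclust]
#'   (default `"complete"`).
#' @return a list: `labels` (integer cluster per row), `order` (dendrogram
#'   leaf order), `hclust` (the tree), `k`.
#' @export
cluster_timecourses <- function(matrix, k, normalize = c("max", "none"),
                                linkage = "complete") {
  normalize <- match.arg(normalize)
  m <- unclass(matrix)
  if (k < 2L) cf_stop("k must be >= 2", class = "citfoot_validation_error")
  if (k > nrow(m)) {
    cf_stop("k exceeds the number of rows", class = "citfoot_validation_error")
  }
  mm <- if (normalize == "max") row_max_normalize(m) else m
  hc <- stats::hclust(stats::dist(mm, method = "euclidean"), method = linkage)
  list(labels = stats::cutree(hc, k = k), order = hc$order, hclust = hc, k = k)
}

#' Mean signal curve with standard errors
#'
#' @param matrix a [timecourse_matrix].
#' @return a data.frame with columns `timepoint`, `mean`, `sem`.
#' @export
mean_signal_curve <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) == 0L) {
    cf_stop("mean_signal_curve needs at least one row",
            class = "citfoot_degenerate_error")
  }
  tp <- attr(matrix, "timepoints") %||% as.numeric(colnames(m))
  sem <- if (nrow(m) == 1L) rep(0, ncol(m)) else
    apply(m, 2L, stats::sd) / sqrt(nrow(m))
  data.frame(timepoint = tp, mean = colMeans(m), sem = sem, row.names = NULL)
}

#' Histogram of time-of-maximum per peak
#'
#' Each row is assigned the earliest timepoint at which it attains its
#' maximum; the histogram of assignments sums to the row count.
#'
#' @param matrix a [timecourse_matrix].
#' @return a list: `assignment` (timepoint per row) and `histogram`
#'   (named count vector over timepoints, zeros included).
#' @export
argmax_timepoint <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) == 0L) {
    cf_stop("argmax_timepoint needs at least one row",
            class = "citfoot_degenerate_error")
  }
  tp <- attr(matrix, "timepoints") %||% as.numeric(colnames(m))
  idx <- apply(m, 1L, which.max)  # which.max takes the earliest tie
  assignment <- tp[idx]
  hist <- stats::setNames(
    vapply(seq_along(tp), function(j) sum(idx == j), integer(1)),
    tp
  )
  list(assignment = assignment, histogram = hist)
}

#' Export a clustered time-course matrix for heatmap plotting
#'
#' Writes the (optionally max-normalized) matrix in dendrogram leaf order
#' with a cluster-label column, so an external plotter reproduces the
#' clustered heatmap.
#'
#' @param matrix a [timecourse_matrix].
#' @param clustering result of [cluster_timecourses].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(matrix, clustering, path) {
  m <- unclass(matrix)[clustering$order, , drop = FALSE]
  df <- data.frame(row = clustering$order,
                   cluster = clustering$labels[clustering$order])
  df <- cbind(df, as.data.frame(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
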