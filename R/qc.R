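# Matrix-level array quality control. Three per-array metrics are scored and
# an array failing more than one of them is removed.

#' Score arrays on matrix-level quality metrics
#'
#' Three non-negative metrics are computed per array:
#' \describe{
#'   \item{distribution_deviation}{Kolmogorov-Smirnov distance between the
#'     array's value distribution and the pooled distribution of all arrays.}
#'   \item{correlation_outlyingness}{1 minus the median Spearman correlation
#'     of the array with every other array.}
#'   \item{rle_spread}{median absolute deviation of the array's relative log
#'     expression (its values minus the per-probeset median across arrays).}
#' }
#' An array is flagged as an outlier on a metric when its value exceeds the
#' upper boxplot fence (Q3 + 1.5 IQR) across arrays, and removed when it
#' fails more than one metric.
#'
#' @param matrix expression matrix (>= 4 arrays).
#' @return data.frame of class `immunet_qc`: one row per array with the
#'   three metric values, per-metric failure flags, `n_failures` and
#'   `removed`.
#' @export
qc_metrics <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 4) {
    stop_immunet("QC needs >= 4 arrays to detect outliers, got %d", ncol(matrix))
  }
  arrays <- colnames(matrix)
  pooled <- sort(as.vector(matrix))
  n_pool <- length(pooled)
  dist_dev <- vapply(arrays, function(a) {
    x <- sort(matrix[, a])
    # KS distance of x's ECDF to the pooled ECDF, evaluated at x's points
    ecdf_pool <- findInterval(x, pooled) / n_pool
    ecdf_x_hi <- seq_along(x) / length(x)
    ecdf_x_lo <- (seq_along(x) - 1) / length(x)
    max(pmax(abs(ecdf_x_hi - ecdf_pool), abs(ecdf_x_lo - ecdf_pool)))
  }, numeric(1))
  sp <- stats::cor(matrix, method = "spearman")
  cor_out <- vapply(seq_along(arrays), function(i) {
    1 - stats::median(sp[i, -i])
  }, numeric(1))
  med <- apply(matrix, 1, stats::median)
  rle_spread <- vapply(arrays, function(a) {
    stats::mad(matrix[, a] - med)
  }, numeric(1))

  fence_fail <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    v > q[2] + 1.5 * (q[2] - q[1])
  }
  fail_dist <- fence_fail(dist_dev)
  fail_cor <- fence_fail(cor_out)
  fail_rle <- fence_fail(rle_spread)
  n_fail <- fail_dist + fail_cor + fail_rle
  out <- data.frame(array_id = arrays,
                    distribution_deviation = dist_dev,
                    correlation_outlyingness = pmax(cor_out, 0),
                    rle_spread = rle_spread,
                    fail_distribution = fail_dist,
                    fail_correlation = fail_cor,
                    fail_rle = fail_rle,
                    n_failures = as.integer(n_fail),
                    removed = n_fail >= 2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("immunet_qc", class(out))
  out
}

#' Drop failing arrays (and depleted datasets) from a compendium
#'
#' Arrays flagged `removed` in the report are dropped from both the matrix
#' and the sample sheet. If a dataset then falls below `min_group_size`
#' arrays, the whole dataset is dropped with a warning.
#'
#' @param matrix expression matrix the report was computed from.
#' @param samples sample sheet covering the matrix arrays.
#' @param report result of [qc_metrics()] on this matrix.
#' @param min_group_size minimum arrays per retained dataset (default 3).
#' @return list with filtered `matrix` and `samples`.
#' @export
qc_filter <- function(matrix, samples, report, min_group_size = 3) {
  if (!setequal(report$array_id, colnames(matrix))) {
    stop_immunet("QC report does not match the matrix arrays")
  }
  drop <- report$array_id[report$removed]
  keep <- setdiff(colnames(matrix), drop)
  if (length(keep) == 0) stop_immunet("QC removed every array")
  samples <- samples[samples$array_id %in% keep, , drop = FALSE]
  sizes <- table(samples$dataset_id)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small) > 0) {
    warning(sprintf("dropping dataset(s) below %d arrays after QC: %s",
                    min_group_size, paste(small, collapse = ", ")),
            call. = FALSE)
    samples <- samples[!samples$dataset_id %in% small, , drop = FALSE]
  }
  if (nrow(samples) == 0) stop_immunet("QC removed every dataset")
  rownames(samples) <- NULL
  list(matrix = matrix[, samples$array_id, drop = FALSE], samples = samples)
}
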