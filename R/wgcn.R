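# Within-group correlation engine and correlation-graph construction.
#
# The edge statistic is the within-group correlation r_w: the per-dataset
# Pearson correlations r_j between two probesets, averaged with weights
# n_j / n proportional to dataset size. Because each r_j is computed within
# one experiment, per-dataset baseline (batch) offsets cancel exactly and
# r_w responds only to co-variation around each experiment's own means --
# in these compendia, chiefly the shared response to that experiment's
# stimulus.

#' Parameters for within-group correlation networks
#'
#' @param threshold minimum r_w for an edge, inclusive (default 0.52).
#' @param min_group_size minimum arrays per dataset (default 3).
#' @param zero_variance_policy what to do when a probeset has zero variance
#'   within a group: `"skip_and_renormalize"` (default) drops that group
#'   from the pair's average and renormalizes the weights over contributing
#'   groups; `"undefined"` makes the pair's r_w undefined if any group is
#'   degenerate.
#' @param chunk_size probesets per block in the pairwise computation
#'   (default 200); bounds working memory, never changes the result.
#' @return validated parameter list of class `wgcn_params`.
#' @export
wgcn_params <- function(threshold = 0.52, min_group_size = 3,
                        zero_variance_policy = c("skip_and_renormalize", "undefined"),
                        chunk_size = 200) {
  zero_variance_policy <- match.arg(zero_variance_policy)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_immunet("threshold must be in (0, 1]")
  }
  if (min_group_size < 2) stop_immunet("min_group_size must be >= 2")
  if (chunk_size < 1) stop_immunet("chunk_size must be >= 1")
  structure(list(threshold = threshold, min_group_size = min_group_size,
                 zero_variance_policy = zero_variance_policy,
                 chunk_size = chunk_size),
            class = "wgcn_params")
}

#' Within-group correlation of two expression vectors
#'
#' Computes `r_w = sum_j r_j * n_j / n`, where `r_j` is the Pearson
#' correlation of `x` and `y` restricted to the arrays of group (dataset)
#' `j`, `n_j` is the group size and `n` the total. Groups where either
#' vector has zero variance are handled by the zero-variance policy; if no
#' group contributes, `NA` is returned.
#'
#' @param x,y numeric vectors in the same array order.
#' @param grouping vector assigning each position to a dataset.
#' @param params a [wgcn_params()].
#' @return r_w in \[-1, 1\], or `NA` if undefined.
#' @export
within_group_correlation <- function(x, y, grouping, params = wgcn_params()) {
  if (length(x) != length(y)) {
    stop_immunet("x and y differ in length (%d vs %d)", length(x), length(y))
  }
  if (length(grouping) != length(x)) {
    stop_immunet("grouping must assign every array (length %d vs %d)",
                 length(grouping), length(x))
  }
  if (any(is.na(grouping))) stop_immunet("grouping contains unassigned arrays")
  groups <- split(seq_along(x), grouping)
  n <- length(x)
  num <- 0
  den <- 0
  for (idx in groups) {
    nj <- length(idx)
    if (nj < params$min_group_size) {
      stop_immunet("group with %d arrays is below min_group_size %d",
                   nj, params$min_group_size)
    }
    sx <- stats::sd(x[idx])
    sy <- stats::sd(y[idx])
    if (sx == 0 || sy == 0) {
      if (params$zero_variance_policy == "undefined") return(NA_real_)
      next
    }
    num <- num + stats::cor(x[idx], y[idx]) * nj / n
    den <- den + nj / n
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Build the thresholded within-group correlation network
#'
#' Computes r_w for every unordered probeset pair (in blocks of
#' `chunk_size` rows to bound memory) and keeps pairs with defined
#' r_w at or above the threshold. Probesets with zero variance in every
#' group are excluded. The edge list is sorted canonically (lexicographic,
#' smaller id first).
#'
#' @param matrix expression matrix.
#' @param samples sample sheet assigning each array to a dataset.
#' @param params a [wgcn_params()].
#' @return edge data.frame (`a`, `b`, `weight`); empty (with a warning) if
#'   no pair passes the threshold.
#' @export
network_from_compendium <- function(matrix, samples, params = wgcn_params()) {
  validate_expression_matrix(matrix)
  samples <- validate_sample_sheet(samples, matrix, params$min_group_size)
  G <- nrow(matrix)
  n <- ncol(matrix)
  groups <- split(seq_len(n), samples$dataset_id)

  # per-group standardized rows: z %*% t(z) over a group = that group's
  # Pearson correlation matrix; zero-variance rows flagged NA
  zmats <- list()
  weights <- numeric(0)
  defined <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    xg <- matrix[, idx, drop = FALSE]
    mu <- rowMeans(xg)
    xc <- xg - mu
    ss <- sqrt(rowSums(xc^2))
    ok <- ss > 0
    z <- xc / ifelse(ok, ss, 1)
    z[!ok, ] <- 0
    zmats[[g]] <- z
    defined[[g]] <- ok
    weights[g] <- length(idx) / n
  }
  all_undefined <- Reduce(`&`, lapply(defined, `!`))
  if (any(all_undefined)) {
    message(sprintf("excluding %d probeset(s) with zero variance in every group",
                    sum(all_undefined)))
  }

  nodes <- rownames(matrix)
  res <- list()
  starts <- seq(1, G, by = params$chunk_size)
  for (s in starts) {
    rows <- s:min(s + params$chunk_size - 1, G)
    num <- matrix(0, length(rows), G)
    den <- matrix(0, length(rows), G)
    for (g in names(groups)) {
      z <- zmats[[g]]
      ok <- defined[[g]]
      r <- z[rows, , drop = FALSE] %*% t(z)
      pair_ok <- outer(ok[rows], ok)
      if (params$zero_variance_policy == "undefined") {
        # a degenerate group poisons the pair entirely
        num <- num + ifelse(pair_ok, r * weights[g], NA)
        den <- den + ifelse(pair_ok, weights[g], NA)
      } else {
        num <- num + ifelse(pair_ok, r, 0) * weights[g]
        den <- den + pair_ok * weights[g]
      }
    }
    rw <- ifelse(!is.na(den) & den > 0, num / den, NA)
    # inclusive threshold with a tiny guard against last-bit rounding
    hits <- which(!is.na(rw) & rw >= params$threshold - 1e-12, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      gi <- rows[hits[, 1]]
      gj <- hits[, 2]
      keep <- gi < gj
      if (any(keep)) {
        res[[length(res) + 1]] <- data.frame(
          a = nodes[gi[keep]], b = nodes[gj[keep]],
          weight = rw[hits][keep], stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(a = character(0), b = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    warning("no probeset pair passes the correlation threshold", call. = FALSE)
  }
  flip <- edges$a > edges$b
  if (any(flip)) {
    tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Full within-group correlation matrix
#'
#' Computes r_w for every probeset pair with the same blocked per-group
#' standardization used by [network_from_compendium()], returning the full
#' symmetric matrix (diagonal 1 where defined). Intended for moderate
#' numbers of probesets; the thresholded network constructor never
#' materializes this matrix.
#'
#' @inheritParams network_from_compendium
#' @return numeric matrix of r_w values (`NA` where undefined).
#' @export
within_group_correlation_matrix <- function(matrix, samples,
                                            params = wgcn_params()) {
  validate_expression_matrix(matrix)
  samples <- validate_sample_sheet(samples, matrix, params$min_group_size)
  G <- nrow(matrix)
  n <- ncol(matrix)
  groups <- split(seq_len(n), samples$dataset_id)
  num <- matrix(0, G, G)
  den <- matrix(0, G, G)
  for (g in names(groups)) {
    idx <- groups[[g]]
    xg <- matrix[, idx, drop = FALSE]
    xc <- xg - rowMeans(xg)
    ss <- sqrt(rowSums(xc^2))
    ok <- ss > 0
    z <- xc / ifelse(ok, ss, 1)
    z[!ok, ] <- 0
    wj <- length(idx) / n
    r <- matrix(0, G, G)
    starts <- seq(1, G, by = params$chunk_size)
    for (s in starts) {
      rows <- s:min(s + params$chunk_size - 1, G)
      r[rows, ] <- z[rows, , drop = FALSE] %*% t(z)
    }
    pair_ok <- outer(ok, ok)
    if (params$zero_variance_policy == "undefined") {
      num <- num + ifelse(pair_ok, r * wj, NA)
      den <- den + ifelse(pair_ok, wj, NA)
    } else {
      num <- num + ifelse(pair_ok, r, 0) * wj
      den <- den + pair_ok * wj
    }
  }
  out <- ifelse(!is.na(den) & den > 0, num / den, NA)
  dimnames(out) <- list(rownames(matrix), rownames(matrix))
  out
}
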