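# Cluster characterization: exact-test enrichment for annotation terms and
# reference gene lists, BH FDR, averaged cluster expression profiles, and
# permutation-based per-dataset activation calls.

#' Two-tailed Fisher / EASE exact probability for a 2x2 table
#'
#' The table is (a = annotated in cluster, m = cluster size, A = annotated
#' in background, N = background size). The two-tailed p is mass-based: the
#' sum of hypergeometric probabilities of all tables with the same margins
#' whose point probability does not exceed that of the observed table. The
#' EASE variant ("modified Fisher's exact test") decrements the observed
#' cell by one before computing, which is conservative whenever the
#' observed overlap lies above the hypergeometric mode (the
#' over-representation side the score is designed for).
#'
#' @param a overlap count.
#' @param m cluster (list) size.
#' @param A background annotation count.
#' @param N background size.
#' @param method `"fisher"` (default) or `"ease"`.
#' @return p-value in \[0, 1\].
#' @export
fisher_two_tailed <- function(a, m, A, N, method = c("fisher", "ease")) {
  method <- match.arg(method)
  if (a < 0 || m < 0 || A < 0 || N < 0 || a > m || a > A || m > N || A > N) {
    stop_immunet("inconsistent 2x2 margins: a=%d m=%d A=%d N=%d", a, m, A, N)
  }
  lo <- max(0, m + A - N)
  hi <- min(m, A)
  if (method == "ease") a <- max(a - 1, lo)
  support <- lo:hi
  mass <- stats::dhyper(support, A, N - A, m)
  obs <- mass[match(a, support)]
  # relative tolerance guards equal-mass tables against rounding
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, preserving the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_immunet("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Term enrichment of every cluster
#'
#' For each (cluster, term) pair with at least one annotated background
#' element, computes the overlap, the fold enrichment
#' `(a/m) / (A/N)`, the two-tailed Fisher p (plus the EASE p as a side
#' column), and BH q-values adjusted within each cluster across its terms.
#'
#' @param assignment an `immunet_clusters` data.frame.
#' @param term_map named list: entity id -> character vector of terms.
#' @param background character vector, the background universe (must
#'   contain every clustered id). Default: all ids in the assignment.
#' @param method p-value reported in `p`: `"fisher"` (default) or `"ease"`.
#' @param fdr_scope `"per_cluster"` (default) applies BH within each
#'   cluster; `"global"` across all rows.
#' @return data.frame of class `immunet_enrichment`, sorted by
#'   (cluster, q, p, term).
#' @export
enrich_clusters <- function(assignment, term_map, background = NULL,
                            method = c("fisher", "ease"),
                            fdr_scope = c("per_cluster", "global")) {
  method <- match.arg(method)
  fdr_scope <- match.arg(fdr_scope)
  background <- unique(background %||% assignment$id)
  clustered <- assignment$id[!is.na(assignment$cluster)]
  missing <- setdiff(clustered, background)
  if (length(missing) > 0) {
    stop_immunet("clustered id(s) missing from background: %s",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  N <- length(background)
  term_of <- term_map[intersect(names(term_map), background)]
  term_counts <- table(unlist(term_of, use.names = FALSE))
  terms <- names(term_counts)                       # every term with A >= 1
  if (length(terms) == 0 || length(clustered) == 0) {
    out <- data.frame(cluster = integer(0), term = character(0),
                      a = integer(0), m = integer(0), A = integer(0),
                      N = integer(0), fold = numeric(0), p = numeric(0),
                      p_ease = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("immunet_enrichment", class(out))
    return(out)
  }
  rows <- list()
  for (cl in sort(unique(assignment$cluster[!is.na(assignment$cluster)]))) {
    members <- cluster_members(assignment, cl)
    m <- length(members)
    member_terms <- unlist(term_map[intersect(members, names(term_map))],
                           use.names = FALSE)
    a_of <- table(factor(member_terms, levels = terms))
    for (t in terms) {
      a <- as.integer(a_of[[t]])
      A <- as.integer(term_counts[[t]])
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, term = t, a = a, m = m, A = A, N = N,
        fold = (a / m) / (A / N),
        p = fisher_two_tailed(a, m, A, N, method = method),
        p_ease = fisher_two_tailed(a, m, A, N, method = "ease"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (fdr_scope == "global") {
    out$q <- bh_fdr(out$p)
  } else {
    out$q <- NA_real_
    for (cl in unique(out$cluster)) {
      sel <- out$cluster == cl
      out$q[sel] <- bh_fdr(out$p[sel])
    }
  }
  out <- out[order(out$cluster, out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("immunet_enrichment", class(out))
  out
}

#' Overlap of a cluster with reference gene sets
#'
#' Fold enrichment and two-tailed exact p of the overlap between a member
#' list and one or more reference sets, with BH across sets.
#'
#' @param members character vector of cluster member ids.
#' @param reference a character vector (one set) or a named list of sets.
#' @param background background universe containing the members.
#' @param method `"fisher"` (default) or `"ease"`.
#' @return data.frame with one row per set: `set`, `a`, `m`, `A`, `N`,
#'   `fold`, `p`, `q`.
#' @export
geneset_overlap <- function(members, reference, background,
                            method = c("fisher", "ease")) {
  method <- match.arg(method)
  if (!is.list(reference)) reference <- list(set = reference)
  background <- unique(background)
  missing <- setdiff(members, background)
  if (length(missing) > 0) {
    stop_immunet("member id(s) missing from background: %s",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  N <- length(background)
  m <- length(unique(members))
  rows <- lapply(names(reference), function(nm) {
    ref <- intersect(unique(reference[[nm]]), background)
    A <- length(ref)
    a <- length(intersect(members, ref))
    data.frame(set = nm, a = a, m = m, A = A, N = N,
               fold = if (A > 0) (a / m) / (A / N) else NA_real_,
               p = if (A > 0) fisher_two_tailed(a, m, A, N, method) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Percentage of cluster members carrying a term
#'
#' @param members character vector of cluster member ids (non-empty).
#' @param term_map named list: entity -> terms.
#' @param term term id, e.g. `"GO:0002376"`.
#' @param digits decimal digits of the reported percentage (default 0).
#' @return percentage, rounded half away from zero.
#' @export
annotated_fraction <- function(members, term_map, term, digits = 0) {
  if (length(members) == 0) stop_immunet("empty cluster")
  has <- vapply(members, function(p) term %in% (term_map[[p]] %||% character(0)),
                logical(1))
  round_half_away(100 * sum(has) / length(members), digits)
}

#' Average expression profile of a cluster
#'
#' In `centered` mode (default) each member's within-dataset mean is
#' subtracted before averaging across members, so the profile shows
#' response relative to each experiment's own baseline; `raw` mode
#' averages raw values.
#'
#' @param matrix expression matrix.
#' @param samples sample sheet for the matrix.
#' @param members cluster member probesets (subset of matrix rows).
#' @param mode `"centered"` (default) or `"raw"`.
#' @return data.frame, one row per array: `array_id`, `dataset_id`,
#'   `condition`, `value`.
#' @export
cluster_profile <- function(matrix, samples, members,
                            mode = c("centered", "raw")) {
  mode <- match.arg(mode)
  if (length(members) == 0) stop_immunet("empty member set")
  bad <- setdiff(members, rownames(matrix))
  if (length(bad) > 0) stop_immunet("member '%s' not in matrix", bad[1])
  samples <- validate_sample_sheet(samples, matrix, min_group_size = 1)
  sub <- matrix[members, , drop = FALSE]
  if (mode == "centered") {
    for (d in unique(samples$dataset_id)) {
      idx <- which(samples$dataset_id == d)
      sub[, idx] <- sub[, idx, drop = FALSE] -
        rowMeans(sub[, idx, drop = FALSE])
    }
  }
  data.frame(array_id = samples$array_id, dataset_id = samples$dataset_id,
             condition = samples$condition, value = colMeans(sub),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-dataset activation calls for a cluster
#'
#' On the centered cluster profile, the activation effect in a dataset is
#' `mean(treated arrays) - mean(control arrays)`. Its one-sided p-value is
#' estimated by permuting condition labels within the dataset:
#' `p = (1 + #\{permuted effect >= observed\}) / (1 + n_permutations)`.
#' A cluster is called activated in a dataset when the effect exceeds
#' `min_effect` and p falls below `alpha`; the effect-size floor (in log2
#' units, in the spirit of fold-change thresholds in differential
#' expression) keeps statistically significant but biologically negligible
#' shifts from being called activation. Datasets lacking either condition
#' are skipped with a warning.
#'
#' @param matrix expression matrix.
#' @param samples sample sheet.
#' @param members cluster member probesets.
#' @param n_permutations label permutations per dataset (default 1000).
#' @param seed integer seed (default 1).
#' @param alpha significance level (default 0.05).
#' @param min_effect minimum activation effect in log2 units (default 0.5,
#'   i.e. half a doubling of the average cluster profile).
#' @return data.frame, one row per dataset: `dataset_id`, `effect`, `p`,
#'   `activated`.
#' @export
activation_calls <- function(matrix, samples, members, n_permutations = 1000,
                             seed = 1L, alpha = 0.05, min_effect = 0.5) {
  prof <- cluster_profile(matrix, samples, members, mode = "centered")
  set.seed(as.integer(seed))
  rows <- list()
  for (d in sort(unique(prof$dataset_id))) {
    sel <- prof$dataset_id == d
    v <- prof$value[sel]
    treated <- prof$condition[sel] == "treated"
    if (!any(treated) || all(treated)) {
      warning(sprintf("dataset '%s' lacks both conditions; skipped", d),
              call. = FALSE)
      next
    }
    effect <- mean(v[treated]) - mean(v[!treated])
    nt <- sum(treated)
    perm <- vapply(seq_len(n_permutations), function(i) {
      lab <- sample(treated)
      mean(v[lab]) - mean(v[!lab])
    }, numeric(1))
    p <- (1 + sum(perm >= effect)) / (1 + n_permutations)
    rows[[length(rows) + 1]] <- data.frame(
      dataset_id = d, effect = effect, p = p,
      activated = effect > min_effect & p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(dataset_id = character(0), effect = numeric(0),
               p = numeric(0), activated = logical(0))
  rownames(out) <- NULL
  out
}
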