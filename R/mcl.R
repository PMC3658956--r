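# Markov Cluster algorithm (MCL) on the weighted correlation graph.
# Implemented from scratch on a dense column-stochastic matrix: alternate
# expansion (matrix squaring, i.e. random-walk flow) and inflation
# (entrywise powering followed by column renormalization, which sharpens
# flow), pruning tiny entries, until the matrix stops changing. Clusters
# are read off the attractor structure of the limit matrix.

#' Parameters for the MCL clustering
#'
#' @param inflation inflation exponent, > 1 (default 1.8). Larger values
#'   give finer clusters.
#' @param expansion expansion power, integer >= 2 (default 2).
#' @param self_loop_policy `"max_incident_weight"` (default; stabilizes
#'   odd-cycle parity) or `"unit"` self loops.
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param convergence_eps stop when the largest entry change is below this
#'   (default 1e-8).
#' @param max_iterations iteration cap (default 200).
#' @param min_cluster_size clusters smaller than this are kept but flagged
#'   unclustered (default 3).
#' @param weighted use edge weights (default TRUE); `FALSE` treats every
#'   edge as weight 1.
#' @return validated parameter list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 1.8, expansion = 2L,
                       self_loop_policy = c("max_incident_weight", "unit"),
                       prune_threshold = 1e-5, convergence_eps = 1e-8,
                       max_iterations = 200L, min_cluster_size = 3L,
                       weighted = TRUE) {
  self_loop_policy <- match.arg(self_loop_policy)
  if (!is.numeric(inflation) || inflation <= 1) {
    stop_immunet("inflation must exceed 1")
  }
  if (expansion < 2 || expansion != floor(expansion)) {
    stop_immunet("expansion must be an integer >= 2")
  }
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop_policy = self_loop_policy,
                 prune_threshold = prune_threshold,
                 convergence_eps = convergence_eps,
                 max_iterations = as.integer(max_iterations),
                 min_cluster_size = as.integer(min_cluster_size),
                 weighted = isTRUE(weighted)),
            class = "mcl_params")
}

#' Run Markov clustering on a weighted edge list
#'
#' Nodes are ordered lexicographically, self loops added per policy, and
#' the adjacency column-normalized to a stochastic flow matrix. Expansion
#' and inflation alternate, with pruning of entries below
#' `prune_threshold`, until the largest entrywise change falls below
#' `convergence_eps`. In the limit matrix, nodes retaining mass on their
#' own diagonal are attractors; attractors connected through surviving flow
#' form attractor sets, and every node is assigned to the attractor set on
#' which its column carries the most mass (ties to the set containing the
#' lexicographically smallest attractor). The whole procedure is
#' deterministic and invariant to edge order.
#'
#' @param edges edge data.frame (`a`, `b`, `weight`), weights > 0.
#' @param params an [mcl_params()].
#' @return data.frame of class `immunet_clusters` with columns `id`,
#'   `cluster` (1-based, `NA` for unclustered nodes) and `cluster_size`.
#'   Numbering follows [renumber_clusters()]: decreasing size, ties by
#'   smallest member id.
#' @export
run_mcl <- function(edges, params = mcl_params()) {
  if (nrow(edges) == 0) {
    out <- data.frame(id = character(0), cluster = integer(0),
                      cluster_size = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("immunet_clusters", class(out))
    return(out)
  }
  if (any(edges$weight <= 0)) {
    stop_immunet("MCL requires positive edge weights (found %.4f)",
                 min(edges$weight))
  }
  nodes <- sort(unique(c(edges$a, edges$b)))
  nn <- length(nodes)
  A <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  w <- if (params$weighted) edges$weight else rep(1, nrow(edges))
  ia <- match(edges$a, nodes)
  ib <- match(edges$b, nodes)
  A[cbind(ia, ib)] <- w
  A[cbind(ib, ia)] <- w
  diag(A) <- if (params$self_loop_policy == "unit") 1 else
    pmax(apply(A, 2, max), .Machine$double.eps)

  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  for (it in seq_len(params$max_iterations)) {
    Mexp <- M
    for (e in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^params$inflation
    Minf <- normalize(Minf)
    Minf[Minf < params$prune_threshold] <- 0
    Minf <- normalize(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < params$convergence_eps) break
  }

  # attractors: nodes keeping mass on their own diagonal
  attractors <- which(diag(M) > params$prune_threshold)
  if (length(attractors) == 0) attractors <- seq_len(nn)
  # attractor sets: connected components of surviving flow among attractors
  sub <- (M[attractors, attractors, drop = FALSE] > 0) |
    t(M[attractors, attractors, drop = FALSE] > 0)
  comp <- components_from_adjacency(sub)
  # assign every node to the attractor set with the largest column mass
  mass <- rowsum(M[attractors, , drop = FALSE], group = comp)  # sets x nodes
  assign_set <- apply(mass, 2, function(col) {
    mx <- max(col)
    cand <- which(col >= mx - 1e-12)
    if (length(cand) > 1) {
      # tie -> set containing the lexicographically smallest attractor
      firsts <- vapply(cand, function(s) min(attractors[comp == s]), numeric(1))
      cand <- cand[which.min(firsts)]
    }
    cand[1]
  })
  out <- data.frame(id = nodes, cluster = as.integer(assign_set),
                    stringsAsFactors = FALSE)
  renumber_clusters(out, min_cluster_size = params$min_cluster_size)
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    frontier <- start
    comp[start] <- cid
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

#' Canonicalize cluster numbering
#'
#' Clusters are renumbered 1..C by strictly non-increasing size, ties
#' broken by the lexicographically smallest member id. Clusters below
#' `min_cluster_size` keep their members but are flagged unclustered
#' (`cluster = NA`). Idempotent.
#'
#' @param assignment data.frame with columns `id` and `cluster`.
#' @param min_cluster_size clusters below this size become unclustered
#'   (default 1, i.e. keep all).
#' @return data.frame of class `immunet_clusters`, sorted by cluster then id.
#' @export
renumber_clusters <- function(assignment, min_cluster_size = 1L) {
  df <- as.data.frame(assignment)[, c("id", "cluster")]
  na_ids <- df$id[is.na(df$cluster)]
  df <- df[!is.na(df$cluster), , drop = FALSE]
  members <- split(df$id, df$cluster)
  if (length(members) > 0) {
    sizes <- lengths(members)
    firsts <- vapply(members, min, character(1))
    ord <- order(-sizes, firsts)
    members <- members[ord]
    keep <- lengths(members) >= min_cluster_size
    newnum <- rep(NA_integer_, length(members))
    newnum[keep] <- seq_len(sum(keep))
    map <- rep(newnum, lengths(members))
    df <- data.frame(id = unlist(members, use.names = FALSE),
                     cluster = map, stringsAsFactors = FALSE)
  }
  if (length(na_ids) > 0) {
    df <- rbind(df, data.frame(id = na_ids, cluster = NA_integer_,
                               stringsAsFactors = FALSE))
  }
  unassigned <- is.na(df$cluster)
  sizes <- table(df$cluster)
  df$cluster_size <- ifelse(unassigned, NA_integer_,
                            as.integer(sizes[as.character(df$cluster)]))
  df <- df[order(df$cluster, df$id, na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("immunet_clusters", class(df))
  df
}

#' Members of one cluster
#' @param assignment an `immunet_clusters` data.frame.
#' @param cluster cluster number.
#' @return character vector of member ids.
#' @export
cluster_members <- function(assignment, cluster) {
  assignment$id[!is.na(assignment$cluster) & assignment$cluster == cluster]
}
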