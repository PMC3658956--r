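# Shared fixtures. Small compendia keep unit tests fast; the default-shape
# compendium (8 datasets x 12 arrays, 800 probesets) is reserved for the
# acceptance checks. Expensive per-seed pipeline runs are cached so several
# acceptance blocks can share them.

small_config <- function(seed = 1L, ...) {
  compendium_config(n_datasets = 4, arrays_per_dataset = 4,
                    n_core = 20, n_subset = 12, n_celltype = 8, n_noise = 120,
                    responding_dataset_fraction = 0.5, seed = seed, ...)
}

# naive per-pair oracle for the within-group correlation: per-group Pearson
# via cor(), weights n_j/n, skip-and-renormalize on zero variance
oracle_rw <- function(x, y, grouping) {
  n <- length(x)
  num <- 0; den <- 0
  for (idx in split(seq_len(n), grouping)) {
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) next
    num <- num + stats::cor(x[idx], y[idx]) * length(idx) / n
    den <- den + length(idx) / n
  }
  if (den == 0) NA_real_ else num / den
}

# brute-force mass-based two-tailed exact p over all feasible tables
oracle_fisher <- function(a, m, A, N) {
  support <- max(0, m + A - N):min(m, A)
  mass <- stats::dhyper(support, A, N - A, m)
  sum(mass[mass <= mass[support == a] * (1 + 1e-7)])
}

# cache of full default-shape pipeline runs keyed by seed
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  comp <- generate_compendium(compendium_config(seed = seed))
  edges <- network_from_compendium(comp$matrix, comp$samples)
  clusters <- run_mcl(edges)
  res <- list(comp = comp, edges = edges, clusters = clusters)
  .acceptance_cache[[key]] <- res
  res
}

# sample one element of a vector even when it has length 1
pick1 <- function(v) v[sample.int(length(v), 1)]
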