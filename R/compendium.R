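# Synthetic multi-experiment compendium generator. Emulates the statistical
# structure the meta-analysis assumes: several independent experiments
# (datasets) with their own baseline (batch) offsets, control/treated arrays
# within each, a planted core-response class responding in every dataset, a
# subset-response class responding in a fraction of datasets, a cell-type
# class with shared per-array abundance but no treatment response, and
# background noise probesets.

#' Configuration for the synthetic compendium
#'
#' All expression quantities are in log2 units. The response model is a
#' shared per-dataset treatment factor times a per-probeset loading, so that
#' probesets of the same planted class co-respond (and are therefore
#' within-group correlated), rather than being independently differentially
#' expressed. The subset and cell-type classes additionally share a latent
#' per-array co-expression factor scaled by `coexpression_sd`; without it a
#' class responding in only a fraction f of datasets could never exceed a
#' within-group correlation of about f.
#'
#' @param n_datasets number of independent experiments (default 8).
#' @param arrays_per_dataset arrays per condition within each dataset
#'   (default 6, i.e. 6 control + 6 treated).
#' @param n_core core-response probesets, responding in every dataset
#'   (default 60).
#' @param n_subset subset-response probesets (default 40).
#' @param responding_dataset_fraction fraction of datasets in which the
#'   subset class responds (default 3/8).
#' @param n_celltype cell-type probesets: tissue-specific baseline and
#'   shared per-array abundance, no treatment response (default 30).
#' @param n_noise background probesets (default 670).
#' @param baseline_mean,baseline_sd per-probeset baseline distribution
#'   (default 7, 1.5).
#' @param batch_sd sd of per-probeset, per-dataset batch offsets (default 1).
#' @param effect_mean,effect_sd distribution of the shared per-dataset
#'   treatment factor (default 2, 0.3).
#' @param gene_loading_sd sd of the per-probeset loading around 1
#'   (default 0.1).
#' @param coexpression_sd scale of the shared per-array latent factor for
#'   the subset and cell-type classes (default 1).
#' @param noise_sd residual sd (default 0.3).
#' @param seed integer seed; identical config implies identical output.
#' @return validated config object of class `compendium_config`.
#' @export
compendium_config <- function(n_datasets = 8, arrays_per_dataset = 6,
                              n_core = 60, n_subset = 40,
                              responding_dataset_fraction = 3 / 8,
                              n_celltype = 30, n_noise = 670,
                              baseline_mean = 7, baseline_sd = 1.5,
                              batch_sd = 1, effect_mean = 2, effect_sd = 0.3,
                              gene_loading_sd = 0.1, coexpression_sd = 1,
                              noise_sd = 0.3, seed = 1L) {
  cfg <- list(n_datasets = n_datasets, arrays_per_dataset = arrays_per_dataset,
              n_core = n_core, n_subset = n_subset,
              responding_dataset_fraction = responding_dataset_fraction,
              n_celltype = n_celltype, n_noise = n_noise,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              batch_sd = batch_sd, effect_mean = effect_mean,
              effect_sd = effect_sd, gene_loading_sd = gene_loading_sd,
              coexpression_sd = coexpression_sd, noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- c("n_datasets", "arrays_per_dataset", "n_core", "n_subset",
              "n_celltype", "n_noise")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      stop_immunet("invalid compendium config: '%s' must be a non-negative integer", f)
    }
  }
  if (cfg$n_datasets < 1) stop_immunet("invalid compendium config: 'n_datasets' must be >= 1")
  if (cfg$arrays_per_dataset < 3) {
    stop_immunet("invalid compendium config: 'arrays_per_dataset' must be >= 3")
  }
  for (f in c("baseline_sd", "batch_sd", "effect_sd", "gene_loading_sd",
              "coexpression_sd", "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) ||
        cfg[[f]] < 0) {
      stop_immunet("invalid compendium config: '%s' must be a non-negative number", f)
    }
  }
  if (cfg$responding_dataset_fraction < 0 || cfg$responding_dataset_fraction > 1) {
    stop_immunet("invalid compendium config: 'responding_dataset_fraction' must be in [0, 1]")
  }
  class(cfg) <- "compendium_config"
  cfg
}

#' Generate a synthetic multi-experiment expression compendium
#'
#' The value for probeset g on array i of dataset d is
#' `baseline_g + batch_{g,d} + loading_g * factor_{class,d} * treated(i) *
#' responds(class, d) + loading_g * coexpression_sd * latent_{class,i} + eps`,
#' with `eps ~ Normal(0, noise_sd)`. All random components are drawn in a
#' fixed order and scaled by their sd afterwards, so regenerating with one
#' sd changed reuses the same underlying draws for every other component.
#'
#' @param config a [compendium_config()].
#' @return list of class `compendium` with elements `matrix` (probesets x
#'   arrays), `samples` (sample sheet data.frame), `term_map` (planted
#'   "immune" term on core probesets plus 20 decoy terms), and `truth`
#'   (planted classes, per-dataset effects, responding datasets).
#' @export
generate_compendium <- function(config = compendium_config()) {
  if (!inherits(config, "compendium_config")) {
    config <- do.call(compendium_config, as.list(config))
  }
  cfg <- config
  D <- cfg$n_datasets
  per <- cfg$arrays_per_dataset
  G <- cfg$n_core + cfg$n_subset + cfg$n_celltype + cfg$n_noise
  if (G < 1) stop_immunet("invalid compendium config: no probesets requested")
  A <- D * 2L * per

  gw <- max(4, nchar(as.character(G)))
  probesets <- sprintf("ps%0*d", gw, seq_len(G))
  classes <- rep(c("core", "subset", "celltype", "noise"),
                 times = c(cfg$n_core, cfg$n_subset, cfg$n_celltype, cfg$n_noise))
  names(classes) <- probesets

  dw <- nchar(as.character(D))
  datasets <- sprintf("d%0*d", dw, seq_len(D))
  tissues <- rep_len(c("blood", "macrophage", "lymph_node"), D)
  samples <- do.call(rbind, lapply(seq_len(D), function(d) {
    data.frame(
      array_id = sprintf("%s_%s%0*d", datasets[d],
                         rep(c("c", "t"), each = per), nchar(as.character(per)),
                         rep(seq_len(per), 2)),
      dataset_id = datasets[d],
      condition = rep(c("control", "treated"), each = per),
      tissue = tissues[d],
      stringsAsFactors = FALSE)
  }))
  treated <- as.numeric(samples$condition == "treated")
  ds_index <- match(samples$dataset_id, datasets)

  set.seed(cfg$seed)
  # fixed draw order; scaling by sd applied after drawing
  baseline <- cfg$baseline_mean + cfg$baseline_sd * stats::rnorm(G)
  batch <- cfg$batch_sd * matrix(stats::rnorm(G * D), G, D)
  loading <- 1 + cfg$gene_loading_sd * stats::rnorm(G)
  f_core <- cfg$effect_mean + cfg$effect_sd * stats::rnorm(D)
  f_subset <- cfg$effect_mean + cfg$effect_sd * stats::rnorm(D)
  # latent co-expression factors are centered within every dataset x
  # condition cell, so planted non-responses are realized exactly: a class
  # with no treatment effect shows zero condition contrast in the sample,
  # not merely in expectation
  cell <- interaction(samples$dataset_id, samples$condition)
  balance <- function(u) u - stats::ave(u, cell)
  latent_subset <- cfg$coexpression_sd * balance(stats::rnorm(A))
  latent_celltype <- cfg$coexpression_sd * balance(stats::rnorm(A))
  tissue_offset <- stats::rnorm(length(unique(tissues)))
  names(tissue_offset) <- unique(tissues)
  n_resp <- round(cfg$responding_dataset_fraction * D)
  responding <- if (n_resp > 0) sort(sample.int(D, n_resp)) else integer(0)
  noise <- cfg$noise_sd * matrix(stats::rnorm(G * A), G, A)

  responds <- matrix(0, G, D)                 # per-probeset, per-dataset factor
  responds[classes == "core", ] <- rep(f_core, each = sum(classes == "core"))
  if (length(responding) > 0) {
    responds[classes == "subset", responding] <-
      rep(f_subset[responding], each = sum(classes == "subset"))
  }

  mat <- matrix(baseline, G, A) + batch[, ds_index, drop = FALSE] + noise
  mat <- mat + (loading * responds[, ds_index, drop = FALSE]) *
    matrix(treated, G, A, byrow = TRUE)
  is_sub <- classes == "subset"
  is_ct <- classes == "celltype"
  mat[is_sub, ] <- mat[is_sub, , drop = FALSE] +
    outer(loading[is_sub], latent_subset)
  mat[is_ct, ] <- mat[is_ct, , drop = FALSE] +
    outer(loading[is_ct], latent_celltype) +
    matrix(tissue_offset[samples$tissue], sum(is_ct), A, byrow = TRUE)
  dimnames(mat) <- list(probesets, samples$array_id)

  term_map <- make_planted_terms(probesets, classes)

  effects <- loading * responds                # planted per-dataset effect sizes
  dimnames(effects) <- list(probesets, datasets)
  truth <- list(class = classes,
                effects = effects,
                responding_datasets = datasets[responding],
                immune_term = "GO:IMMUNE")
  out <- list(matrix = mat, samples = samples, term_map = term_map,
              truth = truth, config = cfg)
  class(out) <- "compendium"
  out
}

# planted "immune" term on core probesets + 20 random decoy terms;
# consumes RNG state (call inside the seeded generator).
make_planted_terms <- function(probesets, classes) {
  terms <- lapply(probesets, function(p) character(0))
  names(terms) <- probesets
  core <- probesets[classes == "core"]
  for (p in core) terms[[p]] <- "GO:IMMUNE"
  for (k in seq_len(20)) {
    members <- sample(probesets, size = max(3, round(0.05 * length(probesets))))
    term <- sprintf("GO:DECOY%02d", k)
    for (p in members) terms[[p]] <- c(terms[[p]], term)
  }
  terms[lengths(terms) > 0]
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("synthetic compendium: %d probesets x %d arrays in %d datasets\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$samples$dataset_id))))
  cat(sprintf("planted classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}

#' Generate a four-species ortholog presence/absence fixture
#'
#' Builds a presence table with an exact number of genes in each requested
#' Venn region. Each region is given as a present-species set and an
#' absent-species set; species named in neither are assigned at random
#' (seeded). A gene is never generated absent from all species.
#'
#' @param region_spec list of regions, each a `list(present =, absent =,
#'   count =)` with species names among `species`.
#' @param seed integer seed for the free-species draws.
#' @param species the species universe (default human, mouse, cow, pig).
#' @return data.frame with column `gene` and one logical column per species.
#' @export
generate_presence_fixture <- function(region_spec, seed = 1L,
                                      species = c("human", "mouse", "cow", "pig")) {
  pats <- lapply(region_spec, function(r) {
    present <- unique(r$present %||% character(0))
    absent <- unique(r$absent %||% character(0))
    bad <- setdiff(c(present, absent), species)
    if (length(bad) > 0) stop_immunet("unknown species '%s' in region spec", bad[1])
    if (length(intersect(present, absent)) > 0) {
      stop_immunet("species '%s' listed both present and absent",
                   intersect(present, absent)[1])
    }
    if (!is.numeric(r$count) || r$count < 0 || r$count != floor(r$count)) {
      stop_immunet("region count must be a non-negative integer")
    }
    list(present = present, absent = absent, count = as.integer(r$count))
  })
  # regions must be pairwise disjoint treating unconstrained species as wildcard
  for (i in seq_along(pats)) {
    for (j in seq_along(pats)) {
      if (i < j) {
        pi <- pats[[i]]; pj <- pats[[j]]
        compatible <- all(vapply(species, function(s) {
          ci <- if (s %in% pi$present) TRUE else if (s %in% pi$absent) FALSE else NA
          cj <- if (s %in% pj$present) TRUE else if (s %in% pj$absent) FALSE else NA
          is.na(ci) || is.na(cj) || ci == cj
        }, logical(1)))
        if (compatible) {
          stop_immunet("region specs %d and %d overlap (not disjoint)", i, j)
        }
      }
    }
  }
  set.seed(as.integer(seed))
  rows <- list()
  gi <- 0L
  for (p in pats) {
    free <- setdiff(species, c(p$present, p$absent))
    for (k in seq_len(p$count)) {
      gi <- gi + 1L
      flags <- stats::setNames(rep(NA, length(species)), species)
      flags[p$present] <- TRUE
      flags[p$absent] <- FALSE
      if (length(free) > 0) flags[free] <- stats::runif(length(free)) < 0.5
      if (!any(flags)) {
        pick <- if (length(free) > 0) sample(free, 1) else
          stop_immunet("region with all species absent requested")
        flags[pick] <- TRUE
      }
      rows[[gi]] <- flags
    }
  }
  out <- as.data.frame(do.call(rbind, rows) %||% matrix(logical(0), 0, length(species),
                                                        dimnames = list(NULL, species)))
  out <- cbind(data.frame(gene = sprintf("gene%04d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Generate duplication candidates with known artifact/true labels
#'
#' Artifactual candidates have nucleotide identity at or above the cutoff
#' and tandem-proximal placement (same scaffold, or same chromosome within
#' the proximity window, or -- for a third of them -- different chromosomes,
#' the "especially problematic" category). True-duplication candidates have
#' identity below the cutoff, or high identity but same-chromosome placement
#' beyond the proximity window.
#'
#' @param n_artifact,n_true counts of each class.
#' @param seed integer seed.
#' @param identity_cutoff,proximity_bp classifier parameters the fixture is
#'   built around (defaults match [classify_duplications()]).
#' @return data.frame of candidates with a `truth` column
#'   (`artifactual`/`true_duplication`).
#' @export
generate_duplication_fixture <- function(n_artifact, n_true, seed = 1L,
                                         identity_cutoff = 98.5,
                                         proximity_bp = 1e6) {
  if (n_artifact < 0 || n_true < 0) stop_immunet("counts must be >= 0")
  set.seed(as.integer(seed))
  mk <- function(i, truth) {
    len <- sample(500:3000, 1)
    start_a <- sample.int(5e7, 1)
    if (truth == "artifactual") {
      identity <- stats::runif(1, identity_cutoff, 100)
      kind <- sample(c("same_scaffold", "same_chrom", "diff_chrom"), 1)
      if (kind == "same_scaffold") {
        chrom <- as.character(sample(1:18, 1))
        scaf <- sprintf("scaffold%03d", sample.int(500, 1))
        start_b <- start_a + len + sample.int(5e4, 1)
        c_a <- chrom; c_b <- chrom; s_a <- scaf; s_b <- scaf
      } else if (kind == "same_chrom") {
        chrom <- as.character(sample(1:18, 1))
        start_b <- start_a + len + sample.int(proximity_bp - len - 1, 1)
        c_a <- chrom; c_b <- chrom
        s_a <- sprintf("scaffold%03d", sample.int(500, 1))
        s_b <- sprintf("scaffold%03d", sample.int(500, 1) + 500)
      } else {
        chroms <- sample(1:18, 2)
        start_b <- sample.int(5e7, 1)
        c_a <- as.character(chroms[1]); c_b <- as.character(chroms[2])
        s_a <- sprintf("scaffold%03d", sample.int(500, 1))
        s_b <- sprintf("scaffold%03d", sample.int(500, 1) + 500)
      }
    } else {
      if (stats::runif(1) < 0.7) {           # diverged copies, any placement
        identity <- stats::runif(1, 70, identity_cutoff - 0.1)
        chroms <- sample(1:18, 2)
        c_a <- as.character(chroms[1]); c_b <- as.character(chroms[2])
      } else {                               # near-identical but distal
        identity <- stats::runif(1, identity_cutoff, 100)
        chrom <- as.character(sample(1:18, 1))
        c_a <- chrom; c_b <- chrom
      }
      start_b <- start_a + len + proximity_bp + sample.int(1e7, 1)
      s_a <- sprintf("scaffold%03d", sample.int(500, 1))
      s_b <- sprintf("scaffold%03d", sample.int(500, 1) + 500)
    }
    data.frame(gene_a = sprintf("gene%03dA", i), gene_b = sprintf("gene%03dB", i),
               identity = identity, chrom_a = c_a, chrom_b = c_b,
               scaffold_a = s_a, scaffold_b = s_b,
               start_a = start_a, end_a = start_a + len,
               start_b = start_b, end_b = start_b + len,
               truth = truth, stringsAsFactors = FALSE)
  }
  n <- n_artifact + n_true
  if (n == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), truth = character(0)))
  }
  labels <- c(rep("artifactual", n_artifact), rep("true_duplication", n_true))
  do.call(rbind, lapply(seq_len(n), function(i) mk(i, labels[i])))
}

#' Corrupt one array of an expression matrix
#'
#' Adds a constant shift and extra Gaussian noise to a single named array,
#' leaving all others untouched. Used to build QC test fixtures.
#'
#' @param matrix expression matrix.
#' @param array_id column to corrupt.
#' @param shift constant added to the array (log2 units).
#' @param extra_noise_sd sd of additional noise (log2 units).
#' @param seed integer seed.
#' @return modified copy of the matrix.
#' @export
corrupt_array <- function(matrix, array_id, shift = 0, extra_noise_sd = 0,
                          seed = 1L) {
  validate_expression_matrix(matrix)
  if (!array_id %in% colnames(matrix)) {
    stop_immunet("unknown array id '%s'", array_id)
  }
  set.seed(as.integer(seed))
  matrix[, array_id] <- matrix[, array_id] + shift +
    extra_noise_sd * stats::rnorm(nrow(matrix))
  matrix
}
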