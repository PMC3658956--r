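# Comparative-immunome computations: gene-family expansion/contraction
# against a reference species, four-species ortholog Venn-region queries,
# assembly-artifact duplication classification, annotation-summary
# aggregation and selection-proportion arithmetic.

COMPARATIVE_SPECIES <- c("human", "mouse", "cow", "pig")

#' Read a gene-family count table
#'
#' TSV with columns `family`, one functional-count column per species and
#' optionally `<species>_pseudo` pseudogene-count columns. Functional and
#' pseudogene counts are kept separate; expansion/contraction uses
#' functional counts only.
#'
#' @param path path to a TSV file.
#' @param species species columns expected (default human, mouse, cow, pig).
#' @return data.frame with integer count columns.
#' @export
read_family_counts <- function(path, species = COMPARATIVE_SPECIES) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, quote = "")
  missing <- setdiff(c("family", species), colnames(df))
  if (length(missing) > 0) {
    stop_immunet("family table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  for (s in c(species, paste0(species, "_pseudo"))) {
    if (s %in% colnames(df)) {
      df[[s]] <- as.integer(df[[s]])
      if (any(is.na(df[[s]]) | df[[s]] < 0)) {
        stop_immunet("column '%s' has a negative or non-integer count", s)
      }
    }
  }
  df
}

#' Classify a family as expanded/contracted per species
#'
#' A species' family is `expanded` when its functional gene count strictly
#' exceeds `(1 + fraction)` times the reference species' count, and
#' `contracted` when strictly below `(1 - fraction)` times it; otherwise
#' `neither`. A family absent from the reference but present in a species
#' counts as expanded; absent from both is `neither`.
#'
#' @param counts named numeric vector of functional counts per species.
#' @param reference_species reference (default `"human"`).
#' @param fraction change fraction defining expansion/contraction
#'   (default 0.25, i.e. ">25%").
#' @return named character vector of statuses for non-reference species.
#' @export
classify_family_change <- function(counts, reference_species = "human",
                                   fraction = 0.25) {
  if (any(counts < 0)) stop_immunet("negative gene count")
  if (!reference_species %in% names(counts)) {
    stop_immunet("reference species '%s' missing from counts", reference_species)
  }
  ref <- counts[[reference_species]]
  others <- setdiff(names(counts), reference_species)
  status <- vapply(others, function(s) {
    v <- counts[[s]]
    if (ref == 0) {
      if (v > 0) "expanded" else "neither"
    } else if (v > (1 + fraction) * ref) {
      "expanded"
    } else if (v < (1 - fraction) * ref) {
      "contracted"
    } else "neither"
  }, character(1))
  stats::setNames(status, others)
}

#' Tally expanded and contracted families per species
#'
#' @param table family count data.frame (see [read_family_counts()]).
#' @param reference_species reference (default `"human"`).
#' @param fraction change fraction (default 0.25).
#' @param row_filter optional logical vector, row indices, or predicate
#'   function on the table selecting which families participate (the row
#'   universe behind a tally is an explicit choice, not a constant).
#' @param species species columns (default human, mouse, cow, pig).
#' @return data.frame: `species`, `expanded`, `contracted`.
#' @export
count_family_changes <- function(table, reference_species = "human",
                                 fraction = 0.25, row_filter = NULL,
                                 species = COMPARATIVE_SPECIES) {
  if (!is.null(row_filter)) {
    if (is.function(row_filter)) {
      table <- table[row_filter(table), , drop = FALSE]
    } else {
      table <- table[row_filter, , drop = FALSE]
    }
  }
  others <- setdiff(species, reference_species)
  tally <- matrix(0L, length(others), 2,
                  dimnames = list(others, c("expanded", "contracted")))
  for (i in seq_len(nrow(table))) {
    counts <- stats::setNames(as.numeric(table[i, species]), species)
    st <- classify_family_change(counts, reference_species, fraction)
    for (s in others) {
      if (st[[s]] %in% colnames(tally)) {
        tally[s, st[[s]]] <- tally[s, st[[s]]] + 1L
      }
    }
  }
  data.frame(species = rownames(tally),
             expanded = tally[, "expanded"],
             contracted = tally[, "contracted"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a four-species presence/absence table
#'
#' TSV with a `gene` column and one column per species holding 0/1 or
#' TRUE/FALSE. Every gene must be present in at least one species.
#'
#' @param path path to TSV.
#' @param species species columns (default human, mouse, cow, pig).
#' @return data.frame with logical species columns.
#' @export
read_presence_table <- function(path, species = COMPARATIVE_SPECIES) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, quote = "")
  missing <- setdiff(c("gene", species), colnames(df))
  if (length(missing) > 0) {
    stop_immunet("presence table lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  for (s in species) df[[s]] <- as.logical(as.integer(as.logical(df[[s]])) == 1)
  validate_presence_table(df, species)
}

validate_presence_table <- function(presence, species = COMPARATIVE_SPECIES) {
  flags <- as.matrix(presence[, species, drop = FALSE])
  if (any(is.na(flags))) stop_immunet("presence table has missing flags")
  if (any(rowSums(flags) == 0)) {
    stop_immunet("gene '%s' absent from every species",
                 presence$gene[rowSums(flags) == 0][1])
  }
  presence
}

#' Count genes matching a presence/absence pattern
#'
#' Number of genes present in all of `present`, absent from all of
#' `absent`, and unconstrained in any remaining species.
#'
#' @param presence presence data.frame (see [read_presence_table()]).
#' @param present species that must carry the gene.
#' @param absent species that must lack it.
#' @param species the species universe.
#' @return integer count.
#' @export
venn_query <- function(presence, present = character(0), absent = character(0),
                       species = COMPARATIVE_SPECIES) {
  if (length(intersect(present, absent)) > 0) {
    stop_immunet("species '%s' requested both present and absent",
                 intersect(present, absent)[1])
  }
  bad <- setdiff(c(present, absent), species)
  if (length(bad) > 0) stop_immunet("unknown species '%s'", bad[1])
  keep <- rep(TRUE, nrow(presence))
  for (s in present) keep <- keep & presence[[s]]
  for (s in absent) keep <- keep & !presence[[s]]
  sum(keep)
}

#' Exclusive Venn region counts
#'
#' Counts of the 15 mutually exclusive non-empty presence patterns; the
#' counts always sum to the number of genes.
#'
#' @param presence presence data.frame.
#' @param species species universe.
#' @return data.frame: `present` (species joined by `+`), `count`.
#' @export
venn_regions <- function(presence, species = COMPARATIVE_SPECIES) {
  validate_presence_table(presence, species)
  flags <- as.matrix(presence[, species, drop = FALSE])
  pattern <- apply(flags, 1, function(f) paste(species[as.logical(f)], collapse = "+"))
  all_patterns <- unlist(lapply(seq_along(species), function(k) {
    utils::combn(species, k, FUN = paste, collapse = "+")
  }))
  counts <- table(factor(pattern, levels = all_patterns))
  data.frame(present = all_patterns, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Classify duplication candidates as artifactual or true duplications
#'
#' A candidate pair is artifactual when its nucleotide identity is at or
#' above `identity_cutoff` and the copies are tandem-proximal: on the same
#' assembly scaffold, or on the same chromosome with nearest coordinates
#' within `proximity_bp`. High-identity pairs on different chromosomes are
#' also classed artifactual (category `diff_chrom`) but flagged as needing
#' directed verification. Everything else is a true duplication.
#' Artifactual categories: `same_chrom_same_scaffold`,
#' `same_chrom_diff_scaffold`, `diff_chrom`.
#'
#' @param candidates data.frame with columns `gene_a`, `gene_b`,
#'   `identity` (percent), `chrom_a`, `chrom_b`, `scaffold_a`,
#'   `scaffold_b`, `start_a`, `end_a`, `start_b`, `end_b`.
#' @param identity_cutoff percent identity at or above which a pair is a
#'   candidate artifact (default 98.5, operationalizing "approximately
#'   99%").
#' @param proximity_bp nearest-coordinate distance defining tandem
#'   proximity (default 1e6).
#' @return list with `calls` (candidates plus `class`, `category`,
#'   `needs_verification`) and `tally` (counts per class/category).
#' @export
classify_duplications <- function(candidates, identity_cutoff = 98.5,
                                  proximity_bp = 1e6) {
  need <- c("gene_a", "gene_b", "identity", "chrom_a", "chrom_b",
            "scaffold_a", "scaffold_b", "start_a", "end_a", "start_b", "end_b")
  missing <- setdiff(need, colnames(candidates))
  if (length(missing) > 0) {
    stop_immunet("duplication table lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  if (any(candidates$identity < 0 | candidates$identity > 100)) {
    stop_immunet("identity must be a percentage in [0, 100]")
  }
  coords <- candidates[, c("start_a", "end_a", "start_b", "end_b")]
  if (any(coords <= 0) || any(candidates$start_a > candidates$end_a) ||
      any(candidates$start_b > candidates$end_b)) {
    stop_immunet("malformed coordinates (must be positive with start <= end)")
  }
  n <- nrow(candidates)
  class <- character(n)
  category <- rep(NA_character_, n)
  verify <- rep(FALSE, n)
  gap <- pmax(0, pmax(candidates$start_a, candidates$start_b) -
                 pmin(candidates$end_a, candidates$end_b))
  for (i in seq_len(n)) {
    hi_id <- candidates$identity[i] >= identity_cutoff
    same_chrom <- candidates$chrom_a[i] == candidates$chrom_b[i]
    same_scaf <- same_chrom && candidates$scaffold_a[i] == candidates$scaffold_b[i]
    if (hi_id && same_scaf) {
      class[i] <- "artifactual"; category[i] <- "same_chrom_same_scaffold"
    } else if (hi_id && same_chrom && gap[i] <= proximity_bp) {
      class[i] <- "artifactual"; category[i] <- "same_chrom_diff_scaffold"
    } else if (hi_id && !same_chrom) {
      class[i] <- "artifactual"; category[i] <- "diff_chrom"; verify[i] <- TRUE
    } else {
      class[i] <- "true_duplication"
    }
  }
  calls <- cbind(candidates,
                 data.frame(class = class, category = category,
                            needs_verification = verify,
                            stringsAsFactors = FALSE))
  tally <- as.data.frame(table(class = class, category = addNA(factor(category)),
                               useNA = "no"), stringsAsFactors = FALSE)
  tally <- tally[tally$Freq > 0, , drop = FALSE]
  rownames(tally) <- NULL
  list(calls = calls, tally = tally)
}

#' Read an annotation summary table
#'
#' TSV with columns `chromosome`, `genes`, `known_genes`, `transcripts`,
#' `protein_coding`, `complete_protein_coding`, `pseudogenes`,
#' `non_organism_supported`.
#'
#' @param path path to TSV.
#' @return data.frame with integer count columns.
#' @export
read_annotation_summary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, quote = "")
  need <- c("chromosome", "genes", "known_genes", "transcripts",
            "protein_coding", "complete_protein_coding", "pseudogenes",
            "non_organism_supported")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0) {
    stop_immunet("annotation summary lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  for (c in need[-1]) df[[c]] <- as.integer(df[[c]])
  df
}

#' Column totals and consistency report for an annotation summary
#'
#' Sums all count columns across chromosomes and reports (without raising)
#' rows violating the internal ordering constraints
#' `complete_protein_coding <= protein_coding <= transcripts` and
#' `known_genes <= genes`.
#'
#' @param rows annotation summary data.frame (see
#'   [read_annotation_summary()]).
#' @return list with `totals` (named integer vector) and `violations`
#'   (data.frame: `chromosome`, `constraint`).
#' @export
summarize_annotation_table <- function(rows) {
  if (nrow(rows) < 1) stop_immunet("annotation summary has no rows")
  countcols <- setdiff(colnames(rows), "chromosome")
  totals <- vapply(rows[countcols], function(v) sum(as.integer(v)), integer(1))
  viol <- list()
  for (i in seq_len(nrow(rows))) {
    if (rows$complete_protein_coding[i] > rows$protein_coding[i]) {
      viol[[length(viol) + 1]] <- data.frame(
        chromosome = rows$chromosome[i],
        constraint = "complete_protein_coding > protein_coding")
    }
    if (rows$protein_coding[i] > rows$transcripts[i]) {
      viol[[length(viol) + 1]] <- data.frame(
        chromosome = rows$chromosome[i],
        constraint = "protein_coding > transcripts")
    }
    if (rows$known_genes[i] > rows$genes[i]) {
      viol[[length(viol) + 1]] <- data.frame(
        chromosome = rows$chromosome[i], constraint = "known_genes > genes")
    }
  }
  violations <- do.call(rbind, viol) %||%
    data.frame(chromosome = character(0), constraint = character(0))
  list(totals = totals, violations = violations)
}

#' Proportions of proteins under positive selection
#'
#' Given q-values (counted strictly below each alpha) or precomputed
#' counts, reports each count and its percentage of the total, rounded
#' half away from zero at the requested precision.
#'
#' @param qvalues numeric q-values in \[0, 1\] (used if `counts` is NULL).
#' @param counts integer counts per alpha, alternative to `qvalues`.
#' @param total total proteins analyzed (> 0).
#' @param alphas significance thresholds (default 0.05, 0.10).
#' @param digits decimal digits of the percentages (default 0).
#' @return data.frame: `alpha`, `count`, `percent`.
#' @export
selection_proportions <- function(qvalues = NULL, counts = NULL, total,
                                  alphas = c(0.05, 0.10), digits = 0) {
  if (total <= 0) stop_immunet("total must be positive")
  if (is.null(counts)) {
    if (is.null(qvalues)) stop_immunet("supply qvalues or counts")
    if (any(qvalues < 0 | qvalues > 1)) stop_immunet("q-values must lie in [0, 1]")
    counts <- vapply(alphas, function(a) sum(qvalues < a), numeric(1))
  }
  if (length(counts) != length(alphas)) {
    stop_immunet("need one count per alpha (%d vs %d)",
                 length(counts), length(alphas))
  }
  if (any(counts > total)) stop_immunet("count exceeds total")
  data.frame(alpha = alphas, count = as.integer(counts),
             percent = round_half_away(100 * counts / total, digits),
             stringsAsFactors = FALSE)
}

#' Read an exclusive Venn-region count file and expand it to a presence table
#'
#' The file has columns `present` (species joined by `+`; all other species
#' absent) and `count`. `expand_venn_regions()` materializes one gene row
#' per counted gene via [generate_presence_fixture()], so
#' [venn_regions()] on the result reproduces the file exactly.
#'
#' @param path path to the region-count TSV.
#' @param species species universe.
#' @return `read_venn_region_counts`: data.frame (`present`, `count`);
#'   `expand_venn_regions`: presence data.frame.
#' @export
read_venn_region_counts <- function(path, species = COMPARATIVE_SPECIES) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, quote = "")
  if (!all(c("present", "count") %in% colnames(df))) {
    stop_immunet("region count file needs columns 'present' and 'count'")
  }
  df$count <- as.integer(df$count)
  df
}

#' @rdname read_venn_region_counts
#' @param regions data.frame as returned by [read_venn_region_counts()].
#' @param seed seed passed to the fixture generator (regions here are fully
#'   specified, so it does not affect the result).
#' @export
expand_venn_regions <- function(regions, species = COMPARATIVE_SPECIES,
                                seed = 1L) {
  spec <- lapply(seq_len(nrow(regions)), function(i) {
    present <- strsplit(regions$present[i], "+", fixed = TRUE)[[1]]
    list(present = present, absent = setdiff(species, present),
         count = regions$count[i])
  })
  generate_presence_fixture(spec, seed = seed, species = species)
}
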