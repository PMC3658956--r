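family_table <- function() {
  read_family_counts(system.file("extdata", "immune_family_counts.tsv",
                                 package = "immunet"))
}

test_that("family expansion/contraction uses strict >25% thresholds on functional counts", {
  tab <- family_table()
  row_of <- function(f) {
    r <- tab[tab$family == f, ]
    stats::setNames(as.numeric(r[, c("human", "mouse", "cow", "pig")]),
                    c("human", "mouse", "cow", "pig"))
  }
  expect_equal(classify_family_change(row_of("Cathelicidin SF"))[["pig"]],
               "expanded")                         # 10 vs 1
  expect_equal(classify_family_change(row_of("C-type Lysozyme/LYZ1 SF"))[["pig"]],
               "neither")                          # 7/9 ~ 0.78 > 0.75
  expect_equal(classify_family_change(
    row_of("ADP-ribosyltransferase/VIP2 SF"))[["mouse"]],
    "neither")                                     # exactly 1.25x: strict
  expect_equal(classify_family_change(
    row_of("Type I Interferon, Delta Subfamily"))[["pig"]],
    "expanded")                                    # reference zero, pig 11
  expect_equal(classify_family_change(c(human = 0, pig = 0))[["pig"]], "neither")
  expect_error(classify_family_change(c(human = -1, pig = 2)), "negative")
})

test_that("tallies match a brute-force per-row re-derivation and support filters", {
  flat <- data.frame(family = c("f1", "f2"),
                     human = c(2, 4), mouse = c(2, 4),
                     cow = c(2, 4), pig = c(4, 2))
  got <- count_family_changes(flat)
  expect_equal(got$expanded[got$species == "pig"], 1)
  expect_equal(got$contracted[got$species == "pig"], 1)
  expect_true(all(got[got$species %in% c("mouse", "cow"), c("expanded", "contracted")] == 0))

  set.seed(41)
  rnd <- data.frame(family = sprintf("f%02d", 1:30),
                    human = sample(0:20, 30, TRUE),
                    mouse = sample(0:20, 30, TRUE),
                    cow = sample(0:20, 30, TRUE),
                    pig = sample(0:20, 30, TRUE))
  got <- count_family_changes(rnd)
  for (s in c("mouse", "cow", "pig")) {
    exp_n <- 0; con_n <- 0
    for (i in 1:30) {
      h <- rnd$human[i]; v <- rnd[[s]][i]
      if ((h == 0 && v > 0) || (h > 0 && v > 1.25 * h)) exp_n <- exp_n + 1
      else if (h > 0 && v < 0.75 * h) con_n <- con_n + 1
    }
    expect_equal(got$expanded[got$species == s], exp_n)
    expect_equal(got$contracted[got$species == s], con_n)
  }
  top <- count_family_changes(rnd, row_filter = function(t) t$family %in% c("f01", "f02"))
  top2 <- count_family_changes(rnd[1:2, ])
  expect_equal(top, top2)

  # scale consistency: doubling all counts changes no status
  rnd2 <- rnd
  rnd2[, c("human", "mouse", "cow", "pig")] <- 2 * rnd2[, c("human", "mouse", "cow", "pig")]
  expect_equal(count_family_changes(rnd2), got)
})

test_that("venn region counts partition the synthetic ortholog table", {
  regions <- read_venn_region_counts(
    system.file("extdata", "ortholog_venn_regions_synthetic.tsv",
                package = "immunet"))
  tab <- expand_venn_regions(regions)
  expect_equal(nrow(tab), 597)
  got <- venn_regions(tab)
  expect_equal(sum(got$count), nrow(tab))
  merged <- merge(got, regions, by = "present")
  expect_equal(merged$count.x, merged$count.y)
  # published marginal queries
  expect_equal(venn_query(tab, c("pig", "cow"), c("human", "mouse")), 18)
  expect_equal(venn_query(tab, c("human", "pig"), "mouse"), 42)
  expect_equal(venn_query(tab, c("human", "mouse"), "pig"), 14)
  expect_equal(venn_query(tab, c("mouse", "pig"), "human"), 7)
  expect_equal(venn_query(tab, c("human", "mouse", "cow", "pig")), 184)
  expect_error(venn_query(tab, "pig", "pig"), "both")
})

test_that("duplication classifier applies the identity and proximity rules", {
  base <- data.frame(gene_a = "gA", gene_b = "gB", identity = 99.5,
                     chrom_a = "3", chrom_b = "3",
                     scaffold_a = "s1", scaffold_b = "s1",
                     start_a = 1000, end_a = 2000,
                     start_b = 2500, end_b = 3500)
  expect_equal(classify_duplications(base)$calls$category,
               "same_chrom_same_scaffold")
  d <- base; d$scaffold_b <- "s2"; d$start_b <- 5e5; d$end_b <- 5.01e5
  expect_equal(classify_duplications(d)$calls$category, "same_chrom_diff_scaffold")
  d2 <- d; d2$start_b <- 5e6; d2$end_b <- 5.01e6   # beyond 1 Mb, same chrom
  expect_equal(classify_duplications(d2)$calls$class, "true_duplication")
  d3 <- base; d3$chrom_b <- "7"; d3$scaffold_b <- "s9"
  got3 <- classify_duplications(d3)$calls
  expect_equal(got3$category, "diff_chrom")
  expect_true(got3$needs_verification)
  il1b <- d3; il1b$identity <- 86                   # diverged true duplicate
  expect_equal(classify_duplications(il1b)$calls$class, "true_duplication")
  # boundary: inclusive at the cutoff, flips just below
  at <- base; at$identity <- 98.5
  expect_equal(classify_duplications(at)$calls$class, "artifactual")
  below <- base; below$identity <- 98.5 - 1e-9
  expect_equal(classify_duplications(below)$calls$class, "true_duplication")
  # symmetric in gene order
  sw <- d3[, ]
  sw[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "scaffold_a", "scaffold_b",
         "start_a", "end_a", "start_b", "end_b")] <-
    d3[, c("gene_b", "gene_a", "chrom_b", "chrom_a", "scaffold_b", "scaffold_a",
           "start_b", "end_b", "start_a", "end_a")]
  expect_equal(classify_duplications(sw)$calls$class,
               classify_duplications(d3)$calls$class)
  bad <- base; bad$start_a <- -5
  expect_error(classify_duplications(bad), "coordinates")
})

test_that("annotation summary totals match the transcribed per-chromosome counts", {
  rows <- read_annotation_summary(
    system.file("extdata", "irag_annotation_summary.tsv", package = "immunet"))
  expect_equal(nrow(rows), 19)
  got <- summarize_annotation_table(rows)
  expect_equal(unname(got$totals["genes"]), 1369)
  expect_equal(unname(got$totals["known_genes"]), 988)
  expect_equal(unname(got$totals["transcripts"]), 3472)
  expect_equal(unname(got$totals["protein_coding"]), 2776)
  expect_equal(unname(got$totals["complete_protein_coding"]), 1554)
  expect_equal(unname(got$totals["pseudogenes"]), 26)
  expect_equal(unname(got$totals["non_organism_supported"]), 1172)
  expect_equal(nrow(got$violations), 0)
  # permutation invariance and violation reporting
  perm <- summarize_annotation_table(rows[sample(nrow(rows)), ])
  expect_equal(perm$totals, got$totals)
  one <- rows[1, ]
  expect_equal(summarize_annotation_table(one)$totals["genes"],
               c(genes = 103))
  one$complete_protein_coding <- one$protein_coding + 1
  expect_equal(nrow(summarize_annotation_table(one)$violations), 1)
})

test_that("selection proportions round as published", {
  got <- selection_proportions(counts = c(37, 42), total = 242)
  expect_equal(got$percent, c(15, 17))
  expect_equal(selection_proportions(counts = 348, total = 8418, alphas = 0.05,
                                     digits = 1)$percent, 4.1)
  allnull <- selection_proportions(qvalues = rep(1, 50), total = 50)
  expect_equal(allnull$percent, c(0, 0))
  qv <- c(0.01, 0.049, 0.05, 0.09, 0.2)
  strict <- selection_proportions(qvalues = qv, total = 5)
  expect_equal(strict$count, c(2L, 4L))    # q < alpha, strictly
  expect_error(selection_proportions(counts = 10, total = 5, alphas = 0.05),
               "exceeds")
})
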