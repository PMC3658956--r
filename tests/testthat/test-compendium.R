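test_that("config validation names the offending field", {
  expect_error(compendium_config(n_datasets = 0), "n_datasets")
  expect_error(compendium_config(arrays_per_dataset = 2), "arrays_per_dataset")
  expect_error(compendium_config(noise_sd = -1), "noise_sd")
  expect_error(compendium_config(n_core = 2.5), "n_core")
  expect_error(compendium_config(responding_dataset_fraction = 1.5),
               "responding_dataset_fraction")
})

test_that("generation is seeded-deterministic and truth partitions the universe", {
  cfg <- small_config(seed = 7)
  a <- generate_compendium(cfg)
  b <- generate_compendium(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$matrix, generate_compendium(small_config(seed = 8))$matrix))
  expect_setequal(names(a$truth$class), rownames(a$matrix))
  expect_equal(unname(table(a$truth$class)[c("core", "subset", "celltype", "noise")]),
               c(20, 12, 8, 120), ignore_attr = TRUE)
  expect_identical(a$samples$array_id, colnames(a$matrix))
})

test_that("with all randomness but batch disabled, probesets are constant within datasets", {
  cfg <- small_config(seed = 3, noise_sd = 0, effect_sd = 0, effect_mean = 0,
                      gene_loading_sd = 0, coexpression_sd = 0)
  comp <- generate_compendium(cfg)
  for (d in unique(comp$samples$dataset_id)) {
    sub <- comp$matrix[, comp$samples$dataset_id == d, drop = FALSE]
    expect_true(all(apply(sub, 1, stats::sd) < 1e-12))
  }
})

test_that("core probesets are strongly within-group correlated under the stated effect", {
  cfg <- compendium_config(effect_mean = 2, noise_sd = 0.3, seed = 11)
  comp <- generate_compendium(cfg)
  core <- names(comp$truth$class)[comp$truth$class == "core"][1:6]
  g <- comp$samples$dataset_id
  rws <- combn(core, 2, function(pr) {
    within_group_correlation(comp$matrix[pr[1], ], comp$matrix[pr[2], ], g)
  })
  expect_gt(mean(rws), 0.9)
})

test_that("noise probesets have near-zero within-group correlation", {
  comp <- generate_compendium(compendium_config(seed = 5))
  noise <- names(comp$truth$class)[comp$truth$class == "noise"]
  set.seed(42)
  pairs <- replicate(100, sample(noise, 2))
  g <- comp$samples$dataset_id
  rws <- apply(pairs, 2, function(pr) {
    within_group_correlation(comp$matrix[pr[1], ], comp$matrix[pr[2], ], g)
  })
  expect_lt(mean(abs(rws)), 0.15)
})

test_that("batch offsets do not change within-group correlations", {
  r_for <- function(batch_sd) {
    comp <- generate_compendium(small_config(seed = 9, batch_sd = batch_sd))
    g <- comp$samples$dataset_id
    ids <- rownames(comp$matrix)[c(1, 2, 25, 60, 100, 140)]
    combn(ids, 2, function(pr) {
      within_group_correlation(comp$matrix[pr[1], ], comp$matrix[pr[2], ], g)
    })
  }
  expect_equal(r_for(0), r_for(5), tolerance = 1e-12)
})

test_that("presence fixture honours region specs exactly", {
  spec <- list(list(present = c("pig", "cow"), absent = c("human", "mouse"),
                    count = 18),
               list(present = c("human", "mouse", "cow", "pig"),
                    absent = character(0), count = 5))
  tab <- generate_presence_fixture(spec, seed = 2)
  expect_equal(nrow(tab), 23)
  expect_equal(venn_query(tab, present = c("pig", "cow"),
                          absent = c("human", "mouse")), 18)
  expect_equal(venn_query(tab, present = c("human", "mouse", "cow", "pig")), 5)
})

test_that("presence fixture rejects contradictory or overlapping specs", {
  expect_error(generate_presence_fixture(list(
    list(present = "pig", absent = "pig", count = 1))), "both present and absent")
  expect_error(generate_presence_fixture(list(
    list(present = "pig", absent = character(0), count = 1),
    list(present = c("pig", "cow"), absent = character(0), count = 1))),
    "overlap")
})

test_that("random region specs are recovered by exhaustive per-gene classification", {
  species <- c("human", "mouse", "cow", "pig")
  set.seed(31)
  # 10 random exclusive regions (full present/absent constraint, so disjoint)
  pats <- sample(setdiff(0:15, 0), 10)
  spec <- lapply(seq_along(pats), function(i) {
    mask <- as.logical(bitwAnd(pats[i], c(1, 2, 4, 8)))
    list(present = species[mask], absent = species[!mask],
         count = sample(0:12, 1))
  })
  tab <- generate_presence_fixture(spec, seed = 77)
  for (r in spec) {
    brute <- sum(vapply(seq_len(nrow(tab)), function(i) {
      all(unlist(tab[i, r$present])) && !any(unlist(tab[i, r$absent]))
    }, logical(1)))
    expect_identical(brute, as.integer(r$count))
    expect_equal(venn_query(tab, r$present, r$absent), r$count)
  }
})

test_that("duplication fixture is labelled consistently with the classifier", {
  fix <- generate_duplication_fixture(n_artifact = 25, n_true = 25, seed = 4)
  calls <- classify_duplications(fix)$calls
  expect_identical(calls$class, fix$truth)
  none <- generate_duplication_fixture(3, 0, seed = 1)
  expect_true(all(classify_duplications(none)$calls$class == "artifactual"))
})

test_that("corrupt_array perturbs only the named array", {
  comp <- generate_compendium(small_config(seed = 2))
  same <- corrupt_array(comp$matrix, "d1_c1", shift = 0, extra_noise_sd = 0)
  expect_equal(same, comp$matrix)
  shifted <- corrupt_array(comp$matrix, "d2_t1", shift = 3, extra_noise_sd = 1,
                           seed = 5)
  expect_equal(shifted[, colnames(shifted) != "d2_t1"],
               comp$matrix[, colnames(comp$matrix) != "d2_t1"])
  expect_gt(mean(shifted[, "d2_t1"] - comp$matrix[, "d2_t1"]), 2)
  expect_error(corrupt_array(comp$matrix, "nope"), "unknown array")
})
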