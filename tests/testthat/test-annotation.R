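test_that("two-tailed exact p matches enumeration on hand-checkable tables", {
  # N=4, A=2, m=2: masses 1/6, 4/6, 1/6 -> two-tailed p at a=2 is 1/3
  expect_equal(fisher_two_tailed(2, 2, 2, 4), 1 / 3, tolerance = 1e-12)
  # perfectly proportional table is the modal table -> p = 1
  expect_equal(fisher_two_tailed(2, 4, 50, 100), 1, tolerance = 1e-12)
  expect_error(fisher_two_tailed(5, 4, 10, 100), "inconsistent")
})

test_that("exact p equals the brute-force oracle for all margins with N <= 60", {
  set.seed(12)
  for (i in 1:300) {
    N <- sample(2:60, 1)
    m <- sample(1:N, 1)
    A <- sample(1:N, 1)
    a <- pick1(max(0, m + A - N):min(m, A))
    expect_equal(fisher_two_tailed(a, m, A, N), oracle_fisher(a, m, A, N),
                 tolerance = 1e-10)
  }
})

test_that("exact p agrees with the reference two-sided test and is margin-symmetric", {
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:80, 1); m <- sample(1:N, 1); A <- sample(1:N, 1)
    a <- pick1(max(0, m + A - N):min(m, A))
    ref <- stats::fisher.test(matrix(c(a, A - a, m - a, N - A - m + a), 2))$p.value
    expect_equal(fisher_two_tailed(a, m, A, N), ref, tolerance = 1e-7)
    expect_equal(fisher_two_tailed(a, m, A, N),
                 fisher_two_tailed(a, A, m, N), tolerance = 1e-12)
  }
})

test_that("EASE decrements the observed cell and is conservative for enrichment", {
  set.seed(14)
  for (i in 1:50) {
    N <- sample(20:100, 1); m <- sample(2:(N - 1), 1); A <- sample(2:(N - 1), 1)
    lo <- max(0, m + A - N); hi <- min(m, A)
    mode <- floor((m + 1) * (A + 1) / (N + 2))
    if (mode + 1 > hi) next
    a <- pick1(seq(mode + 1, hi))   # strictly above the hypergeometric mode
    expect_gte(fisher_two_tailed(a, m, A, N, method = "ease") + 1e-12,
               fisher_two_tailed(a, m, A, N, method = "fisher"))
    if (a - 1 >= lo) {
      expect_equal(fisher_two_tailed(a, m, A, N, method = "ease"),
                   fisher_two_tailed(a - 1, m, A, N), tolerance = 1e-12)
    }
  }
})

test_that("BH follows the step-up rule and a brute-force oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    mten <- length(p)
    o <- order(p)
    brute <- numeric(mten)
    for (r in seq_len(mten)) {
      brute[o[r]] <- min(vapply(r:mten, function(j) p[o[j]] * mten / j,
                                numeric(1)), 1)
    }
    expect_equal(q, brute, tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted-p order
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls empirical false-discovery proportion on all-null simulations", {
  set.seed(16)
  fdp <- replicate(200, {
    q <- bh_fdr(runif(40))
    mean(q < 0.05) # all discoveries are false under the global null
  })
  expect_lte(mean(fdp), 0.05 + 0.05)
})

test_that("cluster enrichment recovers planted terms and handles edge terms", {
  comp <- generate_compendium(small_config(seed = 19))
  edges <- network_from_compendium(comp$matrix, comp$samples)
  cl <- run_mcl(edges)
  enr <- enrich_clusters(cl, comp$term_map, background = rownames(comp$matrix))
  core_cl <- cl$cluster[match(names(comp$truth$class)[comp$truth$class == "core"][1],
                              cl$id)]
  imm <- enr[enr$cluster == core_cl & enr$term == "GO:IMMUNE", ]
  expect_equal(nrow(imm), 1)
  expect_gte(imm$fold, 2)
  expect_lt(imm$q, 0.05)

  # a term annotating the whole background: fold 1, p 1
  tm <- comp$term_map
  for (p in rownames(comp$matrix)) tm[[p]] <- c(tm[[p]], "GO:ALL")
  enr2 <- enrich_clusters(cl, tm, background = rownames(comp$matrix))
  allrows <- enr2[enr2$term == "GO:ALL", ]
  expect_true(all(abs(allrows$fold - 1) < 1e-12))
  expect_true(all(allrows$p == 1))
  # terms absent from the background produce no rows
  expect_false("GO:GHOST" %in% enr2$term)
  expect_error(enrich_clusters(cl, tm, background = cl$id[-1]),
               "missing from background")
  # relabeling probesets leaves the p-values unchanged (only membership matters)
  relab <- stats::setNames(sprintf("q%04d", seq_len(nrow(comp$matrix))),
                           rownames(comp$matrix))
  cl2 <- cl; cl2$id <- unname(relab[cl$id])
  tm2 <- comp$term_map; names(tm2) <- unname(relab[names(tm2)])
  enr3 <- enrich_clusters(cl2, tm2, background = unname(relab))
  expect_equal(sort(enr3$p), sort(enr$p), tolerance = 1e-12)
})

test_that("geneset overlap reports exact folds for degenerate references", {
  members <- sprintf("m%02d", 1:10)
  background <- c(members, sprintf("bg%02d", 1:90))
  full <- geneset_overlap(members, members, background)
  expect_equal(full$fold, 10)          # (m/m)/(m/10m)
  expect_lt(full$p, 1e-4)
  disj <- geneset_overlap(members, sprintf("bg%02d", 1:20), background)
  expect_equal(disj$a, 0)
  expect_equal(disj$fold, 0)
  batch <- geneset_overlap(members, list(hit = members[1:5],
                                         miss = sprintf("bg%02d", 1:5)),
                           background)
  expect_equal(batch$q, bh_fdr(batch$p), tolerance = 1e-12)
})

test_that("annotated fraction rounds half away from zero", {
  tm <- stats::setNames(rep(list("GO:X"), 96), sprintf("g%03d", 1:96))
  members <- sprintf("g%03d", 1:619)
  expect_equal(annotated_fraction(members, tm, "GO:X"), 16)   # 96/619 -> 15.5 -> 16
  expect_equal(annotated_fraction(members[1:96], tm, "GO:X"), 100)
  expect_equal(annotated_fraction(sprintf("h%d", 1:5), tm, "GO:X"), 0)
  expect_error(annotated_fraction(character(0), tm, "GO:X"), "empty")
})

test_that("cluster profiles behave in raw and centered modes", {
  comp <- generate_compendium(small_config(seed = 23))
  one <- rownames(comp$matrix)[1]
  raw <- cluster_profile(comp$matrix, comp$samples, one, mode = "raw")
  expect_equal(raw$value, unname(comp$matrix[one, ]), tolerance = 1e-12)
  core <- names(comp$truth$class)[comp$truth$class == "core"]
  cen <- cluster_profile(comp$matrix, comp$samples, core)
  for (d in unique(cen$dataset_id)) {
    expect_lt(abs(mean(cen$value[cen$dataset_id == d])), 1e-12)
    sub <- cen[cen$dataset_id == d, ]
    expect_gt(mean(sub$value[sub$condition == "treated"]),
              mean(sub$value[sub$condition == "control"]))
  }
  expect_error(cluster_profile(comp$matrix, comp$samples, character(0)), "empty")
})

test_that("activation calls separate planted responders from nulls", {
  comp <- generate_compendium(small_config(seed = 27))
  cls <- comp$truth$class
  act_core <- activation_calls(comp$matrix, comp$samples,
                               names(cls)[cls == "core"], seed = 2)
  expect_true(all(act_core$activated))
  act_sub <- activation_calls(comp$matrix, comp$samples,
                              names(cls)[cls == "subset"], seed = 3)
  expect_setequal(act_sub$dataset_id[act_sub$activated],
                  comp$truth$responding_datasets)
  act_ct <- activation_calls(comp$matrix, comp$samples,
                             names(cls)[cls == "celltype"], seed = 4)
  expect_false(any(act_ct$activated))
  # identical conditions -> zero effect, minimum achievable p is 1/(B+1)
  m <- comp$matrix
  m[, comp$samples$condition == "treated"] <-
    m[, comp$samples$condition == "control"]
  act0 <- activation_calls(m, comp$samples, names(cls)[cls == "core"],
                           n_permutations = 1000, seed = 5)
  expect_true(all(abs(act0$effect) < 1e-12))
  expect_false(any(act0$activated))
  expect_true(all(act_core$p >= 1 / 1001))
  # determinism under a fixed seed
  expect_identical(act_core,
                   activation_calls(comp$matrix, comp$samples,
                                    names(cls)[cls == "core"], seed = 2))
})
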