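# Two tiny deterministic cohorts used across the stage tests. Dataset "t2"
# lacks gene C, so stage 1 must substitute the missing-gene constant for it.
toy_collection <- function() {
  base <- c(1, 2, 3, 4, 5, 6)
  t1 <- make_dataset(list(
    A = base, B = c(1, 2, 3, 4, 5, 7), C = c(2, 1, 4, 3, 6, 5),
    X = base + c(0.1, -0.1, 0.2, -0.2, 0, 0), Y = rev(base), Z = c(2, 4, 1, 5, 3, 6)
  ), dataset_id = "t1")
  t2 <- make_dataset(list(
    A = c(6, 5, 4, 3, 2, 1) + c(0, 0.5, 0, 0.5, 0, 0.5), B = c(5, 6, 3, 4, 1, 2),
    X = c(6, 5.5, 4, 3.5, 2, 1.5), Y = base, Z = c(3, 1, 4, 2, 6, 5)
  ), dataset_id = "t2")
  dataset_collection(list(t1, t2))
}

test_that("stage 1 reproduces hand-computed MGCS and missing-gene constants", {
  coll <- toy_collection()
  init <- gene_module(c("A", "B", "C"), "init")
  s1 <- refine_stage1(coll, init, class_filter = "all")

  # oracle: direct pairwise Pearson on the raw vectors
  d1 <- coll$datasets$t1$values
  r_ab <- cor(d1["A", ], d1["B", ]); r_ac <- cor(d1["A", ], d1["C", ])
  r_bc <- cor(d1["B", ], d1["C", ])
  expect_equal(s1$mgcs_table["A", "t1"], mean(c(r_ab, r_ac)), tolerance = 1e-12)
  expect_equal(s1$mgcs_table["B", "t1"], mean(c(r_ab, r_bc)), tolerance = 1e-12)
  expect_equal(s1$cms[["t1"]], mean(c(r_ab, r_ac, r_bc)), tolerance = 1e-12)

  # C is absent from t2: its cell is 0.5 x CMS of {A,B} there
  d2 <- coll$datasets$t2$values
  cms_t2 <- cor(d2["A", ], d2["B", ])
  expect_equal(s1$constants[["t2"]], 0.5 * cms_t2, tolerance = 1e-12)
  expect_equal(s1$mgcs_table["C", "t2"], 0.5 * cms_t2, tolerance = 1e-12)
  expect_equal(s1$missing$t2, "C")
  # fully present in t1: constant computed but never substituted
  expect_equal(s1$missing$t1, character(0))
})

test_that("stage 2 correlates candidates with the module-average profile", {
  coll <- toy_collection()
  init <- gene_module(c("A", "B"), "init")
  s1 <- refine_stage1(coll, init, class_filter = "all")
  s2 <- refine_stage2(coll, init, s1, class_filter = "all")

  # X was built close to the A/B average in both cohorts
  d1 <- coll$datasets$t1$values
  avg1 <- colMeans(d1[c("A", "B"), ])
  expect_equal(s2$cor_table["X", "t1"], cor(d1["X", ], avg1), tolerance = 1e-12)
  # candidate exactly equal to the module average correlates at 1
  ds_exact <- make_dataset(list(A = c(1, 2, 3, 5), B = c(2, 2, 4, 6),
                                E = c(1.5, 2, 3.5, 5.5), Q = c(5, 1, 4, 2)),
                           dataset_id = "exact")
  coll_e <- dataset_collection(list(ds_exact))
  s1e <- refine_stage1(coll_e, init, class_filter = "all")
  s2e <- refine_stage2(coll_e, init, s1e, class_filter = "all")
  expect_equal(s2e$cor_table["E", "exact"], 1, tolerance = 1e-12)

  # gene C exists only in t1; in t2 its cell is the missing-gene constant
  expect_equal(s2$cor_table["C", "t2"], s1$constants[["t2"]], tolerance = 1e-15)
  # initial genes are retained in the stage-2 table
  expect_true(all(c("A", "B") %in% rownames(s2$cor_table)))
  # the table covers the union universe
  expect_setequal(rownames(s2$cor_table), gene_universe(coll, "union"))
})

test_that("stage 3 combines and re-ranks exactly as the toy enumeration", {
  # toy tables: initial {A:0.3, B:0.1}; candidates {C:0.5, D:0.05}; k = 2
  init_tbl <- matrix(c(0.3, 0.1), nrow = 2,
                     dimnames = list(c("A", "B"), "d1"))
  cand_tbl <- matrix(c(0.5, 0.05), nrow = 2,
                     dimnames = list(c("C", "D"), "d1"))
  res <- anchormod:::combine_rank_select(init_tbl, cand_tbl, k = 2)
  expect_equal(res$refined$members, c("C", "A"))
  expect_equal(res$replaced_count, 1)
  expect_equal(nrow(res$combined_ranking), 4)

  # all candidates below all initial genes: nothing is replaced
  res2 <- anchormod:::combine_rank_select(
    matrix(c(0.5, 0.4), 2, dimnames = list(c("A", "B"), "d1")),
    matrix(c(0.1, 0.05), 2, dimnames = list(c("C", "D"), "d1")), k = 2)
  expect_equal(sort(res2$refined$members), c("A", "B"))
  expect_equal(res2$replaced_count, 0)

  # contract: size k, non-increasing scores, ties lexicographic
  res3 <- anchormod:::combine_rank_select(
    matrix(c(0.2, 0.2), 2, dimnames = list(c("B", "A"), "d1")),
    matrix(c(0.2, 0.9), 2, dimnames = list(c("D", "C"), "d1")), k = 2)
  expect_equal(res3$refined$members, c("C", "A"))  # A/B/D tie -> A first
  expect_true(all(diff(res3$refined$scores) <= 0))
})

test_that("stage 3 on data uses candidate-to-initial correlations with constants", {
  coll <- toy_collection()
  init <- gene_module(c("A", "B"), "init")
  s1 <- refine_stage1(coll, init, class_filter = "all")
  s2 <- refine_stage2(coll, init, s1, class_filter = "all")
  s3 <- refine_stage3(coll, init, s1, s2, k = 2, class_filter = "all")

  expect_length(s3$candidates, 2)
  expect_false(any(c("A", "B") %in% s3$candidates))
  expect_equal(nrow(s3$combined_ranking), 4)  # 2k rows
  expect_true(all(s3$refined$members %in% s3$combined_ranking$gene[1:2]))
  # provenance labels partition the refined module
  expect_equal(sum(s3$combined_ranking$origin == "initial"), 2)
  expect_equal(sum(s3$combined_ranking$origin == "candidate"), 2)
  # candidate MGCS oracle: mean correlation to the present initial genes
  cand <- s3$candidates[1]
  if (cand %in% coll$datasets$t1$genes) {
    d1 <- coll$datasets$t1$values
    expect_equal(s3$candidate_mgcs[cand, "t1"],
                 mean(c(cor(d1[cand, ], d1["A", ]), cor(d1[cand, ], d1["B", ]))),
                 tolerance = 1e-12)
  }
  # C absent from t2: its candidate MGCS there is the constant
  if ("C" %in% s3$candidates) {
    expect_equal(s3$candidate_mgcs["C", "t2"], s1$constants[["t2"]],
                 tolerance = 1e-15)
  }
})

test_that("substituting a constant for a missing gene is local", {
  coll <- toy_collection()
  with_c <- refine_stage1(coll, gene_module(c("A", "B", "C")), class_filter = "all")
  # t2 lacks C; the A/B cells there must be identical to a run without C
  no_c <- refine_stage1(coll, gene_module(c("A", "B")), class_filter = "all")
  expect_equal(with_c$mgcs_table[c("A", "B"), "t2"],
               no_c$mgcs_table[c("A", "B"), "t2"], tolerance = 1e-15)
})

test_that("replacement fraction counts new genes and builds the rank curve", {
  old <- gene_module(sprintf("O%03d", 1:150))
  new_members <- c(sprintf("N%03d", 1:74), sprintf("O%03d", 1:76))
  new <- gene_module(new_members)
  rf <- replacement_fraction(old, new)
  expect_equal(rf$count, 74)
  expect_equal(rf$fraction, 74 / 150)
  expect_equal(rf$curve$cumulative_fraction[74], 1)  # first 74 ranks all new
  expect_equal(rf$curve$cumulative_new[150], 74)

  expect_equal(replacement_fraction(old, old)$fraction, 0)
  disjoint <- gene_module(sprintf("X%03d", 1:10))
  expect_equal(replacement_fraction(old, disjoint)$fraction, 1)
})

test_that("refinement is deterministic and improves planted-gene recall", {
  cfg <- small_config()
  sim <- generate_collection(cfg, seed = 13)
  run1 <- refine(sim$collection, sim$metabolites, c("citrate", "spermine"),
                 k = cfg$module_size)
  run2 <- refine(sim$collection, sim$metabolites, c("citrate", "spermine"),
                 k = cfg$module_size)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(run1$result$refined, f1); write_gmt(run2$result$refined, f2)
  expect_identical(readLines(f1), readLines(f2))

  # aggregate over a few seeds: refinement should not hurt recall on average
  gains <- vapply(1:6, function(s) {
    sim_s <- generate_collection(cfg, seed = 20 + s)
    run_s <- refine(sim_s$collection, sim_s$metabolites,
                    c("citrate", "spermine"), k = cfg$module_size)
    recovery_metrics(run_s$result$refined, sim_s$truth)$recall -
      recovery_metrics(run_s$initial, sim_s$truth)$recall
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("more cohorts carrying the signal do not hurt refined recall", {
  recall_with_n <- function(n_datasets, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- small_config(n_datasets = n_datasets)
      sim <- generate_collection(cfg, seed = s)
      run <- refine(sim$collection, sim$metabolites, c("citrate", "spermine"),
                    k = cfg$module_size)
      recovery_metrics(run$result$refined, sim$truth)$recall
    }, numeric(1)))
  }
  seeds <- 31:42
  expect_gte(recall_with_n(6, seeds), recall_with_n(2, seeds) - 0.02)
})
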