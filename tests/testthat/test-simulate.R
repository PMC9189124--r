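test_that("generated collections honor the configured dimensions", {
  cfg <- small_config()
  sim <- generate_collection(cfg, seed = 2)
  expect_length(sim$collection$datasets, 3)
  anchor <- anchor_dataset(sim$collection)
  expect_equal(length(anchor$genes), cfg$n_genes)
  expect_equal(length(anchor$samples), sum(cfg$samples_per_class))
  # non-anchor cohorts lose the configured missing fraction
  others <- sim$collection$datasets[-1]
  for (d in others) {
    expect_equal(length(d$genes),
                 cfg$n_genes - floor(cfg$missing_fraction * cfg$n_genes))
  }
  expect_equal(sim$metabolites$metabolites, c("citrate", "spermine"))
  expect_equal(sim$metabolites$samples, anchor$samples)
  # ground-truth gene sets are disjoint and in range
  expect_length(intersect(sim$truth$planted, sim$truth$stroma), 0)
  expect_length(intersect(sim$truth$planted, sim$truth$decoys$gene), 0)
  expect_true(all(sim$truth$samples$activity >= 0 & sim$truth$samples$activity <= 1))
  expect_true(all(sim$truth$samples$stroma_fraction >= 0 &
                    sim$truth$samples$stroma_fraction <= 1))

  expect_error(generator_config(n_genes = 50, module_size = 40,
                                stroma_size = 30, n_decoys = 0),
               "exceed")
  expect_error(generator_config(missing_fraction = 1), "missing_fraction")
})

test_that("identical config and seed give byte-identical collections", {
  cfg <- small_config()
  s1 <- generate_collection(cfg, seed = 5)
  s2 <- generate_collection(cfg, seed = 5)
  expect_identical(s1$collection$datasets[[2]]$values,
                   s2$collection$datasets[[2]]$values)
  expect_identical(s1$metabolites$concentrations, s2$metabolites$concentrations)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_collection(cfg, seed = 6)
  expect_false(identical(s1$collection$datasets[[1]]$values,
                         s3$collection$datasets[[1]]$values))
})

test_that("anchor metabolites hit the target mutual correlation on average", {
  cfg <- small_config(n_datasets = 1)
  rs <- vapply(1:20, function(s) {
    sim <- generate_collection(cfg, seed = s)
    stats::cor(sim$metabolites$concentrations["citrate", ],
               sim$metabolites$concentrations["spermine", ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - cfg$target_metab_cor), 0.03)
})

test_that("null collections decouple metabolites from the module", {
  cfg <- small_config(n_datasets = 1)
  mean_abs_r <- vapply(1:20, function(s) {
    sim <- generate_null_collection(cfg, seed = s)
    anchor <- anchor_dataset(sim$collection)
    prof <- unit_sum_average(sim$metabolites, c("citrate", "spermine"))
    cors <- correlate_genes_to_profile(anchor, prof)
    mean(abs(cors$r[cors$gene %in% sim$truth$planted]))
  }, numeric(1))
  expect_lt(mean(mean_abs_r), 0.1)
  # same seed: the null generator is just as reproducible
  n1 <- generate_null_collection(cfg, seed = 3)
  n2 <- generate_null_collection(cfg, seed = 3)
  expect_identical(n1$collection$datasets[[1]]$values,
                   n2$collection$datasets[[1]]$values)
})

test_that("planted genes inter-correlate above background", {
  # Analytic expectation at defaults: pairwise r among planted genes is
  # beta^2 Var(a(1-f)) / (beta^2 Var + sigma^2) ~ 0.04-0.09 over all classes,
  # while background pairs center on 0; assert half the analytic margin.
  sim <- generate_collection(small_config(n_datasets = 1), seed = 8)
  anchor <- anchor_dataset(sim$collection)
  planted_cms <- cms(intra_correlation_table(anchor, sim$truth$planted))
  bkg <- setdiff(anchor$genes, c(sim$truth$planted, sim$truth$stroma,
                                 sim$truth$decoys$gene))
  bkg_cms <- cms(intra_correlation_table(anchor, bkg[1:40]))
  expect_gt(planted_cms - bkg_cms, 0.015)
})

test_that("decoys couple to the activity only inside their host cohort", {
  cfg <- small_config()
  sim <- generate_collection(cfg, seed = 12)
  truth <- sim$truth
  act <- truth$samples
  host_r <- c(); away_r <- c()
  for (i in seq_len(nrow(truth$decoys))) {
    g <- truth$decoys$gene[i]; host <- truth$decoys$host[i]
    for (d in sim$collection$datasets) {
      if (!g %in% d$genes) next
      u <- act$activity[act$dataset_id == d$dataset_id] *
        (1 - act$stroma_fraction[act$dataset_id == d$dataset_id])
      r <- stats::cor(d$values[g, ], u)
      if (d$dataset_id == host) host_r <- c(host_r, r) else away_r <- c(away_r, r)
    }
  }
  expect_gt(mean(host_r), 0.2)
  expect_lt(mean(abs(away_r)), 0.15)
})

test_that("recovery metrics count planted hits and decoys", {
  truth <- list(planted = sprintf("P%02d", 1:10),
                decoys = tibble::tibble(gene = c("D1", "D2"), host = c("a", "b")))
  exact <- recovery_metrics(gene_module(truth$planted), truth)
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  expect_equal(exact$decoy_count, 0L)

  none <- recovery_metrics(gene_module(c("X1", "X2")), truth)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)

  half <- recovery_metrics(gene_module(c(truth$planted[1:5], "X1", "X2", "X3",
                                         "X4", "D1")), truth)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$decoy_count, 1L)
})
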