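test_that("intra-correlation tables are full, symmetric and unit-diagonal", {
  ds <- make_dataset(list(up = c(1, 2, 3), down = c(3, 2, 1), odd = c(1, 3, 2)))
  tab <- intra_correlation_table(ds, c("up", "down", "odd"))
  expect_equal(dim(tab$r), c(3L, 3L))
  expect_equal(unname(diag(tab$r)), rep(1, 3))
  expect_equal(tab$r, t(tab$r), tolerance = 1e-12)
  expect_true(all(tab$r >= -1 - 1e-12 & tab$r <= 1 + 1e-12))
  expect_equal(unname(tab$r["up", "down"]), -1)

  # module genes absent from the platform are recorded, not fatal
  tab2 <- intra_correlation_table(ds, c("up", "down", "ghost"))
  expect_equal(tab2$missing, "ghost")
  expect_equal(length(tab2$genes), 2)

  expect_error(intra_correlation_table(ds, c("up", "ghost")), "fewer than 2")
  # zero-variance genes are dropped with a warning
  ds_flat <- make_dataset(list(up = c(1, 2, 3), down = c(3, 2, 1),
                               flat = c(5, 5, 5)))
  expect_warning(tab3 <- intra_correlation_table(ds_flat, c("up", "down", "flat")),
                 "zero-variance")
  expect_equal(tab3$dropped, "flat")
})

test_that("CMS equals the brute-force mean of off-diagonal Pearson pairs", {
  for (trial in 1:25) {
    ds <- random_dataset(10, 20, seed = 1000 + trial)
    tab <- intra_correlation_table(ds, ds$genes)
    expect_equal(cms(tab), brute_force_cms(ds$values), tolerance = 1e-12)
    # mean of the per-gene decomposition reproduces the CMS exactly
    expect_equal(mean(mgcs(tab)), cms(tab), tolerance = 1e-12)
  }
})

test_that("MGCS is the per-gene row mean excluding the diagonal", {
  # construct a table with known row correlations via a hand-made object
  tab <- structure(
    list(genes = c("A", "B", "C"),
         r = matrix(c(1, 0.4, 0.6,
                      0.4, 1, 0.2,
                      0.6, 0.2, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
         samples_used = 10L, missing = character(), dropped = character(),
         dataset_id = "hand"),
    class = "intra_correlation_table"
  )
  expect_equal(unname(mgcs(tab, "A")), 0.5)            # mean(0.4, 0.6)
  expect_equal(cms(tab), mean(c(0.4, 0.6, 0.2)))       # unique off-diag values
  expect_error(mgcs(tab, "Z"), "not present")

  # identical profiles up to positive affine maps: all correlations 1
  base <- c(1, 4, 2, 8, 5)
  ds <- make_dataset(list(g1 = base, g2 = 2 * base + 3, g3 = 0.1 * base - 7))
  tab2 <- intra_correlation_table(ds, ds$genes)
  expect_equal(cms(tab2), 1, tolerance = 1e-12)
  expect_equal(unname(mgcs(tab2)), rep(1, 3), tolerance = 1e-12)
})

test_that("CMS is invariant to gene order and per-gene positive affine maps", {
  ds <- random_dataset(8, 15, seed = 7)
  tab <- intra_correlation_table(ds, ds$genes)
  ref <- cms(tab)

  shuffled <- intra_correlation_table(ds, rev(ds$genes))
  expect_equal(cms(shuffled), ref, tolerance = 1e-12)

  scaled_vals <- ds$values * runif(8, 0.5, 3) + rnorm(8)
  ds2 <- expression_dataset(scaled_vals, "scaled")
  expect_equal(cms(intra_correlation_table(ds2, ds2$genes)), ref,
               tolerance = 1e-12)
})

test_that("collection-wide evaluation restricts samples and tracks missing genes", {
  d1 <- random_dataset(12, 18, seed = 21, dataset_id = "d1")
  # second dataset lacks two module genes
  d2 <- subset_dataset(random_dataset(12, 18, seed = 22, dataset_id = "d2"),
                       genes = sprintf("G%04d", 3:12))
  d2$dataset_id <- "d2"
  coll <- dataset_collection(list(d1, d2))
  module <- gene_module(sprintf("G%04d", 1:6))
  out <- evaluate_across_collection(coll, module)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_missing, c(0L, 2L))
  expect_equal(out$cms[1],
               cms(intra_correlation_table(d1, module)), tolerance = 1e-15)
  # reduced-set oracle for the dataset with absences
  expect_equal(out$cms[2],
               cms(intra_correlation_table(d2, sprintf("G%04d", 3:6))),
               tolerance = 1e-15)
  expect_equal(mean(out$mgcs[[1]]), out$cms[1], tolerance = 1e-12)

  # a dataset where <2 module genes survive is non-evaluable, not fatal
  d3 <- subset_dataset(d1, genes = sprintf("G%04d", 6:12))
  d3$dataset_id <- "d3"
  out2 <- evaluate_across_collection(dataset_collection(list(d1, d3)),
                                     gene_module(sprintf("G%04d", 1:2)))
  expect_true(out2$evaluable[1])
  expect_false(out2$evaluable[2])
})

test_that("a planted module out-scores random same-size modules everywhere", {
  sim <- generate_collection(small_config(), seed = 5)
  module <- gene_module(sim$truth$planted, "planted")
  for (d in sim$collection$datasets) {
    obs <- cms(intra_correlation_table(d, module, class_filter = "cancer"))
    nd <- random_module_null(d, samples = samples_in_class(d, "cancer"),
                             k = length(sim$truth$planted), n_perm = 100,
                             seed = 99)
    expect_gte(sum(obs > nd$null_cms), 95)
  }
})
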