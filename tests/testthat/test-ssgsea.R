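test_that("running-sum scores match the hand enumeration at alpha = 0", {
  u <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
  # set = two top-ranked: steps 1/2,1/2 in-set vs 1/3 out -> 2.5
  expect_identical(ssgsea_sample(u, c("A", "B"), alpha = 0), 2.5)
  # mirrored set = two bottom-ranked -> -2.5
  expect_identical(ssgsea_sample(u, c("D", "E"), alpha = 0), -2.5)
  # monotone transform of the expression leaves the score unchanged
  expect_identical(ssgsea_sample(u * 2, c("A", "B"), alpha = 0), 2.5)
  expect_identical(ssgsea_sample(exp(u), c("A", "B"), alpha = 0.7),
                   ssgsea_sample(u, c("A", "B"), alpha = 0.7))
  # sign antisymmetry at alpha = 0: reversing the ranking negates the score
  expect_equal(ssgsea_sample(-u, c("A", "B"), alpha = 0),
               -ssgsea_sample(u, c("A", "B"), alpha = 0), tolerance = 1e-12)

  expect_error(ssgsea_sample(u, c("Q", "R")), "does not intersect")
  expect_error(ssgsea_sample(u, names(u)), "whole universe")
  u_bad <- u; u_bad["C"] <- NA
  expect_error(ssgsea_sample(u_bad, "A"), "finite")
})

test_that("weighted scores agree with a literal running-sum oracle", {
  withr::with_seed(101, {
    for (trial in 1:20) {
      n <- sample(10:60, 1)
      expr <- rnorm(n)
      names(expr) <- sprintf("G%03d", sample(1:999, n))
      set <- sample(names(expr), sample(2:(n - 2), 1))
      alpha <- sample(c(0, 0.25, 1), 1)
      expect_equal(ssgsea_sample(expr, set, alpha = alpha),
                   brute_force_ssgsea(expr, set, alpha),
                   tolerance = 1e-12)
    }
  })
})

test_that("moving a set gene up in rank strictly increases the score", {
  u <- c(A = 10, B = 8, C = 6, D = 4, E = 2, F = 1)
  set <- c("D", "F")
  base <- ssgsea_sample(u, set, alpha = 0.25)
  u_up <- u; u_up["D"] <- 9  # D moves above C
  expect_gt(ssgsea_sample(u_up, set, alpha = 0.25), base)
})

test_that("dataset-level scoring is per-sample independent in raw mode", {
  ds <- random_dataset(80, 12, seed = 55)
  mod <- gene_module(ds$genes[1:10], "m")
  sc <- ssgsea_dataset(ds, mod, alpha = 0.25)
  expect_equal(nrow(sc), 12)
  expect_equal(sc$universe_size[1], 80)

  # permuting sample order permutes scores identically
  perm <- c(5, 1, 12, 3, 8, 2, 11, 6, 4, 10, 9, 7)
  ds_perm <- subset_dataset(ds, samples = ds$samples[perm])
  sc_perm <- ssgsea_dataset(ds_perm, mod, alpha = 0.25)
  expect_equal(sc_perm$score, sc$score[perm], tolerance = 1e-12)

  # samples with the module genes shifted up must out-score their twins
  withr::with_seed(77, {
    for (pair in 1:50) {
      x <- rnorm(100)
      names(x) <- sprintf("G%03d", 1:100)
      y <- x
      y[1:10] <- y[1:10] + 2
      expect_gt(ssgsea_sample(y, names(x)[1:10], alpha = 0.25),
                ssgsea_sample(x, names(x)[1:10], alpha = 0.25))
    }
  })
})

test_that("centered mode standardizes genes before ranking", {
  # one gene with a huge baseline dominates every raw ranking; centering
  # removes the baseline so the sample-specific shifts decide the ranks
  m <- rbind(
    big = c(100, 100.1, 99.9),
    a = c(1, 3, -1),
    b = c(0, 2, 1),
    flat = c(5, 5, 5)
  )
  colnames(m) <- paste0("S", 1:3)
  ds <- expression_dataset(m, "c")
  raw <- ssgsea_dataset(ds, gene_module("big"), mode = "raw", alpha = 0)
  cen <- ssgsea_dataset(ds, gene_module("big"), mode = "centered", alpha = 0)
  # raw: "big" is always rank 1 -> identical scores across samples
  expect_equal(length(unique(raw$score)), 1)
  # centered: "big" ranks by its within-gene deviation -> scores differ
  expect_gt(length(unique(cen$score)), 1)
})

test_that("adapted scoring equals plain scoring on identical universes", {
  a <- random_dataset(60, 9, seed = 31, dataset_id = "a")
  b <- random_dataset(60, 7, seed = 32, dataset_id = "b")
  mod <- gene_module(a$genes[1:8], "m")
  pair <- adapted_pair_scores(a, b, mod, alpha = 0.25)
  expect_identical(pair$a$score, ssgsea_dataset(a, mod, alpha = 0.25)$score)
  expect_identical(pair$b$score, ssgsea_dataset(b, mod, alpha = 0.25)$score)

  # dropping a non-module gene from b changes a's scores exactly as a
  # recomputation on the reduced universe (independent oracle path)
  b_red <- subset_dataset(b, genes = setdiff(b$genes, "G0050"))
  pair2 <- adapted_pair_scores(a, b_red, mod, alpha = 0.25)
  a_red <- subset_dataset(a, genes = setdiff(a$genes, "G0050"))
  expect_equal(pair2$a$score, ssgsea_dataset(a_red, mod, alpha = 0.25)$score,
               tolerance = 1e-15)

  # module genes outside the shared universe are dropped and reported
  b_nomod <- subset_dataset(b, genes = setdiff(b$genes, "G0001"))
  pair3 <- adapted_pair_scores(a, b_nomod, mod, alpha = 0.25)
  expect_true("G0001" %in% attr(pair3$a, "dropped_members"))
})

test_that("min-max rescaling hits [0, 1] and ignores affine shifts", {
  expect_equal(minmax01(c(2, 4, 6)), c(0, 0.5, 1))
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(15)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      expect_equal(minmax01(a * x + b), minmax01(x), tolerance = 1e-12)
    }
  })
  expect_error(minmax01(rep(3, 5)), "constant")
})

test_that("score-vs-score correlation joins on sample ids", {
  sc <- tibble::tibble(sample_id = paste0("S", 1:5), score = c(1, 3, 2, 5, 4))
  expect_equal(correlate_signature_scores(sc, sc), 1)
  flipped <- sc; flipped$score <- -sc$score
  expect_equal(correlate_signature_scores(sc, flipped), -1)
  other <- tibble::tibble(sample_id = paste0("T", 1:5), score = 1:5)
  expect_error(correlate_signature_scores(sc, other), "shared samples")
})
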