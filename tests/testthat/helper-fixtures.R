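# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny deterministic dataset from explicit vectors.
make_dataset <- function(vectors, dataset_id = "toy", classes = NULL) {
  mat <- do.call(rbind, vectors)
  rownames(mat) <- names(vectors)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  ann <- tibble::tibble(
    sample_id = colnames(mat),
    tissue_class = if (is.null(classes)) "cancer_low_grade" else classes
  )
  expression_dataset(mat, dataset_id = dataset_id, annotations = ann)
}

# A random dataset (seeded) for property tests.
random_dataset <- function(n_genes, n_samples, seed, dataset_id = "rand",
                           classes = NULL) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
    rownames(mat) <- sprintf("G%04d", seq_len(n_genes))
    colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
    make_dataset(asplit(mat, 1), dataset_id = dataset_id, classes = classes)
  })
}

# Small generator config that keeps simulation-based tests fast.
small_config <- function(...) {
  defaults <- list(
    n_datasets = 3, n_genes = 300, module_size = 40, stroma_size = 30,
    n_decoys = 6,
    samples_per_class = c(normal = 15, cancer_low_grade = 20,
                          cancer_high_grade = 20, metastasis = 8, stroma = 6)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# Brute-force CMS oracle: double loop over gene pairs.
brute_force_cms <- function(mat) {
  m <- nrow(mat)
  total <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) total <- total + stats::cor(mat[i, ], mat[j, ])
    }
  }
  total / (m * (m - 1))
}

# Brute-force ssGSEA oracle: literal running-sum enumeration.
brute_force_ssgsea <- function(expression, set, alpha) {
  genes <- names(expression)
  ord <- order(-expression, genes)
  ranked <- genes[ord]
  n <- length(ranked)
  in_set <- ranked %in% set
  m <- sum(in_set)
  w <- (n - seq_len(n) + 1)^alpha
  denom_in <- sum(w[in_set])
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + w[i] / denom_in else p_out <- p_out + 1 / (n - m)
    score <- score + (p_in - p_out)
  }
  score
}
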