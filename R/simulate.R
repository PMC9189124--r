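#' Configuration for the synthetic multi-cohort generator
#'
#' The generator emulates the structure that a metabolite-anchored signature
#' pipeline has to cope with: one anchor cohort with paired expression and
#' two highly mutually correlated metabolite profiles driven by a latent
#' per-sample secretion activity; additional expression-only cohorts that
#' share most but not all genes; a planted co-expressed module tied to the
#' activity; an anti-correlated stroma module; dataset-specific decoy genes
#' coupled to the activity only inside one host cohort; and sample classes
#' with decreasing activity from normal epithelium through low- and
#' high-grade cancer to metastasis, confounded by per-sample stroma content.
#'
#' Per-sample structure: latent activity `a` is drawn around its class mean
#' and stroma fraction `f` around its class mean (both jittered, clamped to
#' \[0, 1\]). Bulk signal is diluted by stroma, so planted genes follow
#' `x = mu_g + beta * a * (1 - f) + N(0, sigma)`, stroma genes
#' `x = mu_g + beta * f + N(0, sigma)`, decoys follow the planted model in
#' their host dataset only, and background genes are pure noise around
#' their baseline.
#'
#' The anchor metabolites are `base + kappa * a * (1 - f) + c + e_i` with a
#' shared per-sample deviation `c` and independent measurement noise `e_i`
#' of sd `metab_noise_sd`; `Var(c)` is calibrated analytically so the
#' mutual metabolite correlation hits `target_metab_cor` (see the methods
#' vignette). Under the null generator (`kappa = 0`) the two metabolites
#' remain mutually correlated but carry no information about the activity.
#'
#' @param n_datasets Number of cohorts (default 12; the first is the anchor).
#' @param n_genes Genes per cohort before platform dropout (default 2000).
#' @param samples_per_class Named counts per tissue class (defaults:
#'   normal 20, cancer_low_grade 30, cancer_high_grade 30, metastasis 10,
#'   stroma 10).
#' @param module_size Planted secretion-module size (default 150).
#' @param stroma_size Stroma-module size (default 100).
#' @param n_decoys Dataset-specific decoy genes, assigned to host cohorts
#'   round-robin (default 30).
#' @param beta Expression effect size of the latent drivers (default 1.0).
#' @param sigma Expression noise sd (default 1.0).
#' @param kappa Metabolite coupling to the activity (default 2.0).
#' @param metab_noise_sd Independent metabolite measurement noise
#'   (default 0.15).
#' @param missing_fraction Fraction of genes dropped at random from each
#'   non-anchor cohort, emulating platform differences (default 0.05).
#' @param target_metab_cor Target mutual correlation of the two anchor
#'   metabolites (default 0.95).
#' @param activity_means,fraction_means Class means of the latent activity
#'   and the stroma fraction.
#' @param activity_jitter_sd,fraction_jitter_sd Within-class jitter sds.
#' @param baseline_mean,baseline_sd Per-gene baseline expression
#'   distribution (log-scale units).
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_datasets = 12, n_genes = 2000,
                             samples_per_class = c(normal = 20,
                                                   cancer_low_grade = 30,
                                                   cancer_high_grade = 30,
                                                   metastasis = 10,
                                                   stroma = 10),
                             module_size = 150, stroma_size = 100,
                             n_decoys = 30,
                             beta = 1.0, sigma = 1.0, kappa = 2.0,
                             metab_noise_sd = 0.15,
                             missing_fraction = 0.05,
                             target_metab_cor = 0.95,
                             activity_means = c(normal = 0.9,
                                                cancer_low_grade = 0.6,
                                                cancer_high_grade = 0.3,
                                                metastasis = 0.1,
                                                stroma = 0.0),
                             fraction_means = c(normal = 0.40,
                                                cancer_low_grade = 0.25,
                                                cancer_high_grade = 0.15,
                                                metastasis = 0.10,
                                                stroma = 0.90),
                             activity_jitter_sd = 0.15,
                             fraction_jitter_sd = 0.1,
                             baseline_mean = 6, baseline_sd = 1) {
  cfg <- list(
    n_datasets = n_datasets, n_genes = n_genes,
    samples_per_class = samples_per_class,
    module_size = module_size, stroma_size = stroma_size, n_decoys = n_decoys,
    beta = beta, sigma = sigma, kappa = kappa,
    metab_noise_sd = metab_noise_sd,
    missing_fraction = missing_fraction,
    target_metab_cor = target_metab_cor,
    activity_means = activity_means, fraction_means = fraction_means,
    activity_jitter_sd = activity_jitter_sd,
    fraction_jitter_sd = fraction_jitter_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd
  )
  validate_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_datasets, cfg$n_genes, cfg$samples_per_class,
              cfg$module_size, cfg$stroma_size)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  }
  if (cfg$module_size + cfg$stroma_size + cfg$n_decoys > cfg$n_genes) {
    stop("planted + stroma + decoys exceed n_genes", call. = FALSE)
  }
  if (cfg$sigma <= 0 || cfg$metab_noise_sd <= 0) {
    stop("noise sds must be positive", call. = FALSE)
  }
  classes <- names(cfg$samples_per_class)
  if (!all(classes %in% tissue_classes)) stop("unknown class in samples_per_class",
                                              call. = FALSE)
  if (!all(classes %in% names(cfg$activity_means)) ||
      !all(classes %in% names(cfg$fraction_means))) {
    stop("activity_means / fraction_means must cover every sampled class",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic multi-cohort collection with ground truth
#'
#' See [generator_config()] for the generative model. Output is
#' deterministic given `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (RNG state local to the call).
#'
#' @return A list with `collection` ([dataset_collection], anchor first),
#'   `metabolites` ([metabolite_table] of citrate and spermine for the
#'   anchor samples) and `truth` (list: `planted`, `stroma`, `decoys`
#'   tibble with `gene` + `host`, and `samples`, a tibble of per-sample
#'   `dataset_id`, `sample_id`, `tissue_class`, `activity`,
#'   `stroma_fraction`).
#' @export
generate_collection <- function(config = generator_config(), seed = 1) {
  validate_config(config)
  withr::with_seed(seed, generate_collection_impl(config))
}

#' Null variant: metabolites decoupled from the latent activity
#'
#' Identical to [generate_collection()] except the metabolite coupling
#' `kappa` is forced to 0, so the anchor metabolites carry no information
#' about the planted module. The calibrated shared deviation keeps the two
#' metabolites mutually correlated.
#'
#' @inheritParams generate_collection
#' @return As [generate_collection()].
#' @export
generate_null_collection <- function(config = generator_config(), seed = 1) {
  config$kappa <- 0
  validate_config(config)
  withr::with_seed(seed, generate_collection_impl(config))
}

generate_collection_impl <- function(cfg) {
  n_bkg <- cfg$n_genes - cfg$module_size - cfg$stroma_size - cfg$n_decoys
  planted <- sprintf("PLT%04d", seq_len(cfg$module_size))
  stroma_genes <- sprintf("STR%04d", seq_len(cfg$stroma_size))
  decoy_genes <- if (cfg$n_decoys > 0) sprintf("DCY%04d", seq_len(cfg$n_decoys)) else character()
  background <- sprintf("BKG%04d", seq_len(n_bkg))
  genes <- c(planted, stroma_genes, decoy_genes, background)
  dataset_ids <- sprintf("D%02d", seq_len(cfg$n_datasets))
  decoy_host <- if (cfg$n_decoys > 0) {
    dataset_ids[((seq_len(cfg$n_decoys) - 1) %% cfg$n_datasets) + 1]
  } else character()

  classes <- rep(names(cfg$samples_per_class), times = cfg$samples_per_class)
  n_samp <- length(classes)

  datasets <- list()
  sample_truth <- list()
  anchor_u <- NULL
  for (di in seq_along(dataset_ids)) {
    id <- dataset_ids[[di]]
    sample_ids <- sprintf("%s_S%03d", id, seq_len(n_samp))
    a <- clamp01(cfg$activity_means[classes] + stats::rnorm(n_samp, 0, cfg$activity_jitter_sd))
    f <- clamp01(cfg$fraction_means[classes] + stats::rnorm(n_samp, 0, cfg$fraction_jitter_sd))
    u <- a * (1 - f)
    mu_g <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    x <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, cfg$sigma),
                nrow = cfg$n_genes, ncol = n_samp)
    x <- x + mu_g
    x[seq_len(cfg$module_size), ] <-
      x[seq_len(cfg$module_size), ] + rep(cfg$beta * u, each = cfg$module_size)
    str_rows <- cfg$module_size + seq_len(cfg$stroma_size)
    x[str_rows, ] <- x[str_rows, ] + rep(cfg$beta * f, each = cfg$stroma_size)
    if (cfg$n_decoys > 0) {
      hosted <- which(decoy_host == id)
      if (length(hosted)) {
        dec_rows <- cfg$module_size + cfg$stroma_size + hosted
        x[dec_rows, ] <- x[dec_rows, ] + rep(cfg$beta * u, each = length(dec_rows))
      }
    }
    rownames(x) <- genes
    colnames(x) <- sample_ids
    keep_genes <- genes
    if (di > 1 && cfg$missing_fraction > 0) {
      n_drop <- floor(cfg$missing_fraction * cfg$n_genes)
      drop <- sample(genes, n_drop)
      keep_genes <- setdiff(genes, drop)
    }
    ann <- tibble::tibble(sample_id = sample_ids, tissue_class = classes,
                          tumor_fraction = 1 - f)
    datasets[[id]] <- expression_dataset(x[keep_genes, , drop = FALSE],
                                         dataset_id = id, annotations = ann)
    sample_truth[[id]] <- tibble::tibble(
      dataset_id = id, sample_id = sample_ids, tissue_class = classes,
      activity = unname(a), stroma_fraction = unname(f)
    )
    if (di == 1) anchor_u <- u
  }

  # Metabolites for the anchor cohort. Mutual correlation target rho:
  #   cor = (kappa^2 V + s^2) / (kappa^2 V + s^2 + tau^2)
  # with V = Var(u) over anchor samples, tau = metab_noise_sd and s the sd of
  # the shared deviation, so s^2 = tau^2 * rho / (1 - rho) - kappa^2 V
  # (floored at 0 when the activity signal alone already exceeds the target).
  v_u <- stats::var(anchor_u)
  tau <- cfg$metab_noise_sd
  s2 <- max(0, tau^2 * cfg$target_metab_cor / (1 - cfg$target_metab_cor) -
              cfg$kappa^2 * v_u)
  shared_dev <- stats::rnorm(n_samp, 0, sqrt(s2))
  base <- 1
  conc <- rbind(
    citrate = base + cfg$kappa * anchor_u + shared_dev + stats::rnorm(n_samp, 0, tau),
    spermine = base + cfg$kappa * anchor_u + shared_dev + stats::rnorm(n_samp, 0, tau)
  )
  conc <- pmax(conc, 0)
  colnames(conc) <- datasets[[1]]$samples
  metab <- metabolite_table(conc)

  truth <- list(
    planted = planted,
    stroma = stroma_genes,
    decoys = tibble::tibble(gene = decoy_genes, host = decoy_host),
    samples = dplyr::bind_rows(sample_truth)
  )
  list(
    collection = dataset_collection(unname(datasets), anchor_id = dataset_ids[[1]]),
    metabolites = metab,
    truth = truth
  )
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Precision/recall of a module against the planted ground truth
#'
#' @param module A [gene_module] or character vector.
#' @param truth Ground-truth list from [generate_collection()].
#' @return A tibble with one row: `precision`, `recall`, `decoy_count`,
#'   `n_module`, `n_planted`.
#' @export
recovery_metrics <- function(module, truth) {
  members <- module_members(module)
  hit <- sum(members %in% truth$planted)
  tibble::tibble(
    precision = if (length(members)) hit / length(members) else NA_real_,
    recall = if (length(truth$planted)) hit / length(truth$planted) else NA_real_,
    decoy_count = sum(members %in% truth$decoys$gene),
    n_module = length(members),
    n_planted = length(truth$planted)
  )
}

#' Small collection with a constructed hub gene
#'
#' Builds cohorts in which one gene is the common driver of a block of
#' module genes: the hub tracks a latent factor almost noiselessly and each
#' driven gene loads on the same factor with its own moderate loading, so
#' every driven gene correlates more strongly with the hub than with its
#' peers. Used to validate hub recovery in the top-k correlation network.
#'
#' @param n_datasets Number of cohorts (default 3).
#' @param n_module Total module genes (default 60); the first is the hub,
#'   the next `n_driven` are driven, the rest are independent noise genes.
#' @param n_driven Driven genes (default 30).
#' @param n_samples Samples per cohort, all cancer-class (default 50).
#' @param seed Integer seed.
#'
#' @return A list with `collection`, `module` ([gene_module]) and `hub`
#'   (the hub gene id).
#' @export
generate_hub_collection <- function(n_datasets = 3, n_module = 60,
                                    n_driven = 30, n_samples = 50, seed = 1) {
  stopifnot(n_driven + 1 < n_module)
  withr::with_seed(seed, {
    hub <- "HUB0001"
    driven <- sprintf("DRV%04d", seq_len(n_driven))
    noise_genes <- sprintf("NSE%04d", seq_len(n_module - n_driven - 1))
    genes <- c(hub, driven, noise_genes)
    datasets <- lapply(seq_len(n_datasets), function(di) {
      id <- sprintf("H%02d", di)
      h <- stats::rnorm(n_samples)
      loadings <- stats::runif(n_driven, 0.4, 0.9)
      x <- rbind(
        h + stats::rnorm(n_samples, 0, 0.1),
        loadings %o% h + matrix(stats::rnorm(n_driven * n_samples),
                                nrow = n_driven),
        matrix(stats::rnorm(length(noise_genes) * n_samples),
               nrow = length(noise_genes))
      )
      rownames(x) <- genes
      colnames(x) <- sprintf("%s_S%03d", id, seq_len(n_samples))
      expression_dataset(x, dataset_id = id,
                         annotations = tibble::tibble(
                           sample_id = colnames(x),
                           tissue_class = "cancer_low_grade"))
    })
    list(collection = dataset_collection(datasets),
         module = gene_module(genes, name = "hub_module"),
         hub = hub)
  })
}
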