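#' Shuffled-profile permutation null for the module CMS
#'
#' The null asks: how big a CMS would the top-k selection produce if the
#' metabolite profile carried no information about the samples? For each
#' permutation the anchor profile's values are randomly shuffled across
#' samples, a fresh top-k module is selected from the gene-profile
#' correlations, and that module's CMS on the same samples is recorded.
#' This mirrors how the observed module was derived, so selection bias
#' (picking the k most-correlated of many genes) is present in the null
#' exactly as in the observation.
#'
#' @param anchor An [expression_dataset] (the cohort with paired metabolite
#'   data).
#' @param profile An `anchor_profile` ([unit_sum_average()]).
#' @param samples Sample ids to use (default: all shared with the profile).
#' @param k Module size per permutation (default 150).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed; the RNG state is local to this call.
#' @param observed_cms Optional observed CMS; when given, the lognormal tail
#'   p-value is attached.
#'
#' @return Object of class `null_distribution`: list with `null_cms`
#'   (length `n_perm`), `mu_hat`, `sigma_hat`, `p` (NA unless
#'   `observed_cms` given), `observed`, `seed`, `n_perm`.
#' @export
permutation_null <- function(anchor, profile, samples = NULL, k = 150,
                             n_perm = 100, seed = 1, observed_cms = NULL) {
  stopifnot(n_perm >= 2)
  shared <- intersect(anchor$samples, profile$samples)
  if (!is.null(samples)) shared <- intersect(samples, shared)
  if (length(shared) < 3) stop("need >=3 shared samples", call. = FALSE)
  p_obs <- profile$values[match(shared, profile$samples)]
  x <- anchor$values[, shared, drop = FALSE]
  null_cms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p_shuf <- sample(p_obs)
      r <- pearson_to_vector(x, p_shuf)
      cor_tbl <- tibble::tibble(gene = anchor$genes, r = r)
      mod <- select_top_k(cor_tbl, k = k, name = "perm")
      tab <- intra_correlation_table(anchor, mod, samples = shared)
      cms(tab)
    }, numeric(1))
  })
  finish_null(null_cms, observed_cms, seed, n_perm)
}

#' Random-gene-module null for the module CMS
#'
#' Alternative null: CMS of `n_perm` uniformly drawn size-k gene sets in the
#' same dataset and samples. Unlike [permutation_null()] it does not model
#' the top-k selection step, so it answers a weaker question (is the module
#' more coherent than an arbitrary gene set?).
#'
#' @inheritParams permutation_null
#' @param dataset The [expression_dataset] to draw modules from.
#' @return A `null_distribution` (see [permutation_null()]).
#' @export
random_module_null <- function(dataset, samples = NULL, k = 150,
                               n_perm = 100, seed = 1, observed_cms = NULL) {
  stopifnot(n_perm >= 2)
  if (is.null(samples)) samples <- dataset$samples
  null_cms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mod <- sample(dataset$genes, k)
      tab <- intra_correlation_table(dataset, mod, samples = samples)
      cms(tab)
    }, numeric(1))
  })
  finish_null(null_cms, observed_cms, seed, n_perm)
}

finish_null <- function(null_cms, observed_cms, seed, n_perm) {
  fit <- if (all(null_cms > 0) && !is.null(observed_cms) && observed_cms > 0) {
    lognormal_p(null_cms, observed_cms)
  } else if (all(null_cms > 0)) {
    c(lognormal_fit(null_cms), p = NA_real_)
  } else {
    list(mu_hat = NA_real_, sigma_hat = NA_real_, p = NA_real_)
  }
  structure(
    list(null_cms = null_cms, mu_hat = fit[["mu_hat"]],
         sigma_hat = fit[["sigma_hat"]], p = fit[["p"]],
         observed = if (is.null(observed_cms)) NA_real_ else observed_cms,
         seed = seed, n_perm = n_perm),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_perm, " permutations (seed ", x$seed, ")\n",
      sep = "")
  cat("  null CMS range: [", format(min(x$null_cms), digits = 3), ", ",
      format(max(x$null_cms), digits = 3), "]\n", sep = "")
  if (!is.na(x$p)) {
    cat("  observed ", format(x$observed, digits = 3), ", lognormal p = ",
        format(x$p, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

lognormal_fit <- function(null_values) {
  lx <- log(null_values)
  mu_hat <- mean(lx)
  sigma_hat <- sqrt(mean((lx - mu_hat)^2))  # MLE: population variance
  if (sigma_hat == 0) stop("zero variance on the log scale: cannot fit lognormal",
                           call. = FALSE)
  c(mu_hat = mu_hat, sigma_hat = sigma_hat)
}

#' Lognormal upper-tail p-value for an observed score
#'
#' Fits a two-parameter lognormal to the null values by maximum likelihood
#' on the log scale (`mu_hat` = mean of logs, `sigma_hat` = population
#' standard deviation of logs) and returns the upper-tail probability of the
#' observed value under the fitted distribution. This parametric tail gives
#' resolution beyond 1 / n_perm, which matters with only 100 permutations.
#'
#' @param null_values Positive null scores (at least two distinct values).
#' @param observed Positive observed score.
#' @return Named numeric vector `c(mu_hat, sigma_hat, p)`.
#' @export
lognormal_p <- function(null_values, observed) {
  if (any(null_values <= 0)) stop("lognormal null requires positive values", call. = FALSE)
  if (length(observed) != 1 || observed <= 0) stop("observed must be a single positive value",
                                                  call. = FALSE)
  fit <- lognormal_fit(null_values)
  p <- stats::pnorm(log(observed), mean = fit[["mu_hat"]], sd = fit[["sigma_hat"]],
                    lower.tail = FALSE)
  c(fit, p = p)
}
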