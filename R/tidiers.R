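#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intra-correlation table into long pairwise form
#'
#' @param x An [intra_correlation_table()] result.
#' @param ... Unused.
#' @return Tibble with `gene_a`, `gene_b`, `r` (all ordered pairs incl.
#'   the diagonal).
#' @method tidy intra_correlation_table
#' @export
tidy.intra_correlation_table <- function(x, ...) {
  tibble::tibble(
    gene_a = rep(x$genes, times = length(x$genes)),
    gene_b = rep(x$genes, each = length(x$genes)),
    r = as.vector(x$r)
  )
}

#' @rdname tidy.intra_correlation_table
#' @method glance intra_correlation_table
#' @export
glance.intra_correlation_table <- function(x, ...) {
  m <- length(x$genes)
  tibble::tibble(
    dataset_id = x$dataset_id, n_genes = m, n_cells = m^2,
    samples_used = x$samples_used, n_missing = length(x$missing),
    cms = cms(x)
  )
}

#' Tidy a permutation null distribution
#'
#' @param x A `null_distribution` (see [permutation_null()]).
#' @param ... Unused.
#' @return One row per permutation: `perm`, `null_cms`.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$null_cms), null_cms = x$null_cms)
}

#' @rdname tidy.null_distribution
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm, observed = x$observed,
    mu_hat = x$mu_hat, sigma_hat = x$sigma_hat, p_value = x$p, seed = x$seed
  )
}

#' Tidy a refinement result
#'
#' @param x A `refinement_result` (see [refine_stage3()]).
#' @param ... Unused.
#' @return The 2k-gene combined ranking with a `selected` flag.
#' @method tidy refinement_result
#' @export
tidy.refinement_result <- function(x, ...) {
  out <- x$combined_ranking
  out$selected <- out$gene %in% x$refined$members
  out
}

#' @rdname tidy.refinement_result
#' @method glance refinement_result
#' @export
glance.refinement_result <- function(x, ...) {
  tibble::tibble(
    k = length(x$refined$members),
    replaced_count = x$replaced_count,
    replaced_fraction = x$replaced_fraction
  )
}

#' Tidy a full refinement run
#'
#' @param x A `refine_run` (see [refine()]).
#' @param ... Unused.
#' @return The per-dataset before/after CMS report.
#' @method tidy refine_run
#' @export
tidy.refine_run <- function(x, ...) x$report

#' @rdname tidy.refine_run
#' @method glance refine_run
#' @export
glance.refine_run <- function(x, ...) {
  g <- glance(x$result)
  g$p_value <- if (!is.null(x$null)) x$null$p else NA_real_
  g
}

#' Tidy a hub ranking
#'
#' @param x A `hub_ranking` (see [hub_ranking()]).
#' @param ... Unused.
#' @return The per-gene mean-degree table.
#' @method tidy hub_ranking
#' @export
tidy.hub_ranking <- function(x, ...) x$table

#' @rdname tidy.hub_ranking
#' @method glance hub_ranking
#' @export
glance.hub_ranking <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(x$networks), k = x$k, n_hubs = x$n_hubs
  )
}

#' Tidy a two-group comparison
#'
#' @param x A `group_comparison` (see [compare_groups()]).
#' @param ... Unused.
#' @return Per-group summary rows.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    difference = x$difference, statistic = x$statistic,
    df = x$df, p_value = x$p_value
  )
}
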