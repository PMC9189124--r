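#' Unit-sum average of metabolite concentration profiles
#'
#' Each named metabolite profile is normalized to sum to one across the
#' chosen samples, then the normalized profiles are averaged elementwise;
#' the result again sums to one. This is the anchor profile that seeds the
#' gene signature (for prostate, the averaged citrate-spermine profile).
#' Normalizing first makes the average scale-invariant per metabolite, so
#' metabolites quantified in different units contribute equally.
#'
#' @param table A [metabolite_table].
#' @param metabolites One or more metabolite names present in the table.
#' @param samples Sample ids to use (default: all samples in the table).
#'
#' @return An object of class `anchor_profile`: list with `samples`,
#'   `values` (nonnegative, summing to one) and `constituents`.
#' @export
unit_sum_average <- function(table, metabolites, samples = NULL) {
  stopifnot(inherits(table, "metabolite_table"), length(metabolites) >= 1)
  unknown <- setdiff(metabolites, table$metabolites)
  if (length(unknown)) stop("unknown metabolite: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (is.null(samples)) samples <- table$samples
  missing_s <- setdiff(samples, table$samples)
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "),
                              call. = FALSE)
  sub <- table$concentrations[metabolites, samples, drop = FALSE]
  sums <- rowSums(sub)
  if (any(sums <= 0)) {
    stop("metabolite profile with zero sum over the chosen samples: ",
         paste(metabolites[sums <= 0], collapse = ", "), call. = FALSE)
  }
  normalized <- sub / sums
  values <- colMeans(normalized)
  structure(list(samples = samples, values = values, constituents = metabolites),
            class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat("<anchor_profile> average of", paste(x$constituents, collapse = " + "),
      "over", length(x$samples), "samples (unit sum)\n")
  invisible(x)
}

#' Correlate every gene with the anchor profile
#'
#' Pearson correlation between each gene's expression profile and the anchor
#' metabolite profile over the shared samples. Genes with zero expression
#' variance get `NA` (Pearson is undefined for them) and are ineligible for
#' selection by [select_top_k()].
#'
#' @param dataset An [expression_dataset].
#' @param profile An `anchor_profile` (see [unit_sum_average()]).
#' @param samples Optional sample ids to restrict to; defaults to all
#'   samples shared between dataset and profile.
#'
#' @return A tibble with columns `gene` and `r`, in dataset gene order.
#' @export
correlate_genes_to_profile <- function(dataset, profile, samples = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(profile, "anchor_profile"))
  shared <- intersect(dataset$samples, profile$samples)
  if (!is.null(samples)) shared <- intersect(samples, shared)
  if (length(shared) < 3) {
    stop("need >=3 shared samples between dataset and profile, got ",
         length(shared), call. = FALSE)
  }
  p <- profile$values[match(shared, profile$samples)]
  if (stats::sd(p) == 0) stop("anchor profile has zero variance over the chosen samples",
                              call. = FALSE)
  x <- dataset$values[, shared, drop = FALSE]
  r <- pearson_to_vector(x, p)
  tibble::tibble(gene = dataset$genes, r = r)
}

# Row-wise Pearson correlation of matrix `x` (genes x samples) with vector
# `y`; rows with zero variance give NA.
pearson_to_vector <- function(x, y) {
  n <- length(y)
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(xc %*% yc) / (sx * sy)
  r[sx == 0] <- NA_real_
  r
}

#' Select the top-k genes by anchor correlation
#'
#' Orders genes by correlation descending and keeps the first `k`; ties at
#' any rank are broken lexicographically by gene id so the selection is
#' deterministic across platforms. Genes with undefined (`NA`) correlation
#' are ineligible.
#'
#' @param correlations Tibble with columns `gene`, `r`
#'   (from [correlate_genes_to_profile()]).
#' @param k Module size; the headline signature uses `k = 150`.
#' @param name Name for the resulting module.
#'
#' @return A [gene_module] of exactly `k` members with `scores` = the
#'   correlations, non-increasing.
#' @export
select_top_k <- function(correlations, k = 150, name = "initial") {
  stopifnot(is.data.frame(correlations),
            all(c("gene", "r") %in% names(correlations)),
            k >= 1)
  ok <- !is.na(correlations$r)
  if (sum(ok) < k) {
    stop("only ", sum(ok), " genes with defined correlation; need k = ", k,
         call. = FALSE)
  }
  tbl <- correlations[ok, ]
  ord <- order(-tbl$r, tbl$gene)
  top <- tbl[ord[seq_len(k)], ]
  gene_module(top$gene, name = name, scores = top$r)
}

#' Derive the initial anchor-correlated module from a collection
#'
#' Convenience wrapper: build the anchor profile from the metabolite table,
#' correlate all anchor-dataset genes with it over the class-filtered
#' samples, and keep the top `k`.
#'
#' @param collection A [dataset_collection].
#' @param metab A [metabolite_table] for the anchor dataset.
#' @param metabolites Metabolite names to average (e.g.
#'   `c("citrate", "spermine")`).
#' @param k Module size (default 150).
#' @param class_filter Samples used for the correlations; default
#'   `"cancer"`.
#' @param name Module name.
#'
#' @return A list with `module` ([gene_module]), `profile`
#'   (`anchor_profile`) and `correlations` (tibble).
#' @export
derive_initial_module <- function(collection, metab, metabolites,
                                  k = 150, class_filter = "cancer",
                                  name = "initial") {
  anchor <- anchor_dataset(collection)
  samples <- samples_in_class(anchor, class_filter)
  samples <- intersect(samples, metab$samples)
  profile <- unit_sum_average(metab, metabolites, samples = samples)
  correlations <- correlate_genes_to_profile(anchor, profile, samples = samples)
  module <- select_top_k(correlations, k = k, name = name)
  list(module = module, profile = profile, correlations = correlations)
}
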