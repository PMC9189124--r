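#' Single-sample GSEA score for one sample
#'
#' The sample's genes are ranked by expression in descending order (ties
#' broken lexicographically by gene id). Walking down the ranking, the score
#' accumulates the difference between the weighted in-set empirical CDF and
#' the out-of-set empirical CDF, summed over every rank position. In-set
#' steps at rank position i are weighted by the rank magnitude
#' (N - i + 1)^alpha, so with alpha > 0 genes high in the ranking count
#' more; alpha = 0 gives equal steps of 1/|set|. The statistic is purely
#' rank-based: any strictly increasing transform of the expression values
#' leaves it unchanged.
#'
#' @param expression Named numeric vector: one sample's expression over the
#'   gene universe (>= 2 genes, all finite).
#' @param gene_set A [gene_module] or character vector of gene ids. The
#'   effective set is its intersection with the universe; it must be
#'   non-empty and must not cover the whole universe.
#' @param alpha Rank-weight exponent (>= 0; default 0.25).
#' @param normalize If TRUE, divide the score by the number of rank
#'   positions (universe size) for comparability across universes.
#'
#' @return A single numeric score.
#' @export
ssgsea_sample <- function(expression, gene_set, alpha = 0.25, normalize = FALSE) {
  genes <- names(expression)
  if (is.null(genes) || length(genes) < 2) {
    stop("expression must be a named vector over >=2 genes", call. = FALSE)
  }
  if (!all(is.finite(expression))) stop("non-finite expression values", call. = FALSE)
  members <- module_members(gene_set)
  in_set <- genes %in% members
  m <- sum(in_set)
  n <- length(genes)
  if (m == 0) stop("gene set does not intersect the universe", call. = FALSE)
  if (m == n) stop("gene set equals the whole universe", call. = FALSE)
  ord <- order(-expression, genes)
  in_ord <- in_set[ord]
  w <- (n - seq_len(n) + 1)^alpha
  w_in <- ifelse(in_ord, w, 0)
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_ord) / (n - m)
  score <- sum(p_in - p_out)
  if (normalize) score <- score / n
  score
}

#' ssGSEA scores for every sample of a dataset
#'
#' Scores each sample independently with [ssgsea_sample()]. In `raw` mode
#' (the default) the expression values are used as loaded — absolute
#' expression level drives the ranking, appropriate when the module tracks a
#' dominating biological feature of the samples. In `centered` mode each
#' gene is z-scored across samples before ranking (genes with zero variance
#' are centered to 0), which is the right choice for sparse per-pixel data
#' or cohorts distributed only as centered values.
#'
#' @param dataset An [expression_dataset].
#' @param module A [gene_module] (or character vector).
#' @param mode `"raw"` or `"centered"`.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide scores by universe size (default FALSE).
#' @param universe Optional gene ids restricting the universe (used by the
#'   adapted cross-dataset mode).
#'
#' @return A tibble of class `enrichment_scores` with columns `sample_id`,
#'   `module`, `score`, `universe_size`, `mode`, `alpha` and attributes
#'   `dataset_id`, `universe` (the gene ids actually used) and
#'   `dropped_members` (module genes outside the universe).
#' @export
ssgsea_dataset <- function(dataset, module, mode = c("raw", "centered"),
                           alpha = 0.25, normalize = FALSE, universe = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "expression_dataset"))
  members <- module_members(module)
  module_name <- if (inherits(module, "gene_module")) module$name else "module"
  genes <- if (is.null(universe)) dataset$genes else intersect(dataset$genes, universe)
  if (length(genes) < 2) stop("universe must contain >=2 dataset genes", call. = FALSE)
  eff_members <- intersect(members, genes)
  if (length(eff_members) == 0) stop("module does not intersect the universe", call. = FALSE)
  x <- dataset$values[genes, , drop = FALSE]
  if (mode == "centered") {
    mu <- rowMeans(x)
    sd_ <- apply(x, 1, stats::sd)
    sd_[sd_ == 0] <- 1
    x <- (x - mu) / sd_
  }
  scores <- vapply(seq_along(dataset$samples), function(j) {
    v <- x[, j]
    names(v) <- genes
    ssgsea_sample(v, eff_members, alpha = alpha, normalize = normalize)
  }, numeric(1))
  out <- tibble::tibble(
    sample_id = dataset$samples,
    module = module_name,
    score = scores,
    universe_size = length(genes),
    mode = mode,
    alpha = alpha
  )
  attr(out, "dataset_id") <- dataset$dataset_id
  attr(out, "universe") <- genes
  attr(out, "dropped_members") <- setdiff(members, eff_members)
  class(out) <- c("enrichment_scores", class(out))
  out
}

#' Adapted cross-dataset ssGSEA: score two cohorts on their shared universe
#'
#' ssGSEA magnitudes depend on the size of the gene universe and of the
#' set, so scores from cohorts profiled on different platforms are not
#' directly comparable. The adapted mode restricts both cohorts to the
#' genes they share (and the module to its members inside that shared
#' universe) before scoring, making universe and set identical on both
#' sides. Optionally one side's scores are min-max rescaled to \[0, 1\]
#' with [minmax01()].
#'
#' @param dataset_a,dataset_b Two [expression_dataset]s.
#' @param module A [gene_module].
#' @param alpha Rank-weight exponent (default 0.25).
#' @param mode `"raw"` or `"centered"` (applied to both).
#' @param minmax `"none"`, `"a"`, `"b"` or `"both"`: which side's scores to
#'   rescale to \[0, 1\].
#'
#' @return A list with `a` and `b`, each an `enrichment_scores` tibble
#'   scored on the shared universe; module genes dropped from the shared
#'   universe are recorded in the `dropped_members` attribute.
#' @export
adapted_pair_scores <- function(dataset_a, dataset_b, module, alpha = 0.25,
                                mode = "raw", minmax = c("none", "a", "b", "both")) {
  minmax <- match.arg(minmax)
  shared <- intersect(dataset_a$genes, dataset_b$genes)
  if (length(shared) < 2) stop("shared gene universe has fewer than 2 genes", call. = FALSE)
  members <- module_members(module)
  if (!length(intersect(members, shared))) {
    stop("module does not intersect the shared universe", call. = FALSE)
  }
  score_a <- ssgsea_dataset(dataset_a, module, mode = mode, alpha = alpha,
                            universe = shared)
  score_b <- ssgsea_dataset(dataset_b, module, mode = mode, alpha = alpha,
                            universe = shared)
  if (minmax %in% c("a", "both")) score_a$score <- minmax01(score_a$score)
  if (minmax %in% c("b", "both")) score_b$score <- minmax01(score_b$score)
  list(a = score_a, b = score_b)
}

#' Min-max rescale to the unit interval
#'
#' `(x - min) / (max - min)`: the smallest value maps to 0 and the largest
#' to 1. Invariant to positive affine transforms of the input.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Rescaled vector in \[0, 1\].
#' @export
minmax01 <- function(scores) {
  rng <- range(scores)
  if (!all(is.finite(rng))) stop("non-finite scores", call. = FALSE)
  if (rng[1] == rng[2]) stop("constant vector cannot be min-max rescaled", call. = FALSE)
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Pearson correlation between two per-sample score sets
#'
#' Joins the two score tables on `sample_id` and correlates the scores —
#' e.g. a secretion-signature score against a stroma-signature score to
#' quantify the stromal confounding of bulk samples.
#'
#' @param scores_a,scores_b `enrichment_scores` tibbles (or any data frame
#'   with `sample_id` and `score`).
#' @return A single Pearson r.
#' @export
correlate_signature_scores <- function(scores_a, scores_b) {
  stopifnot(all(c("sample_id", "score") %in% names(scores_a)),
            all(c("sample_id", "score") %in% names(scores_b)))
  shared <- intersect(scores_a$sample_id, scores_b$sample_id)
  if (length(shared) < 3) {
    stop("need >=3 shared samples, got ", length(shared), call. = FALSE)
  }
  a <- scores_a$score[match(shared, scores_a$sample_id)]
  b <- scores_b$score[match(shared, scores_b$sample_id)]
  stats::cor(a, b)
}
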