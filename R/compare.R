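#' Welch two-sample comparison of enrichment scores
#'
#' Plumbing-level comparison of per-sample scores between two groups using
#' Welch's unequal-variance t-test. This is a self-contained stand-in for a
#' moderated differential model; it reports plain two-sided p-values with
#' no multiple-testing correction.
#'
#' @param scores An `enrichment_scores` tibble (or any data frame with
#'   `sample_id` and `score`).
#' @param groups Either a named character vector (names = sample ids,
#'   values = group labels) or a data frame with columns `sample_id` and
#'   `group`; exactly two levels, each with >= 2 scored samples.
#'
#' @return Object of class `group_comparison`: list with `groups` (tibble
#'   `group`, `n`, `mean`, `sd`), `difference` (mean of group 1 minus mean
#'   of group 2, in label sort order), `statistic`, `df` and `p_value`.
#' @export
compare_groups <- function(scores, groups) {
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    g <- stats::setNames(as.character(groups$group), groups$sample_id)
  } else {
    g <- groups
  }
  lab <- g[scores$sample_id]
  keep <- !is.na(lab)
  x <- scores$score[keep]; lab <- lab[keep]
  levels_ <- sort(unique(lab))
  if (length(levels_) != 2) stop("need exactly two groups, got ", length(levels_),
                                 call. = FALSE)
  x1 <- x[lab == levels_[1]]; x2 <- x[lab == levels_[2]]
  if (length(x1) < 2 || length(x2) < 2) {
    stop("each group needs >=2 scored samples", call. = FALSE)
  }
  summary_tbl <- tibble::tibble(
    group = levels_,
    n = c(length(x1), length(x2)),
    mean = c(mean(x1), mean(x2)),
    sd = c(stats::sd(x1), stats::sd(x2))
  )
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    # degenerate: Welch statistic undefined; identical constants are a null
    identical_means <- isTRUE(all.equal(mean(x1), mean(x2)))
    tt <- list(statistic = c(t = if (identical_means) 0 else Inf),
               parameter = c(df = NA_real_),
               p.value = if (identical_means) 1 else 0)
  } else {
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
  }
  structure(
    list(groups = summary_tbl,
         difference = mean(x1) - mean(x2),
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$groups$group[1], " vs ", x$groups$group[2],
      ": difference ", format(x$difference, digits = 3),
      ", Welch p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Spearman trend of scores along an ordered class sequence
#'
#' Quantifies a monotone trajectory of enrichment scores across ordered
#' disease stages (e.g. normal -> low-grade -> high-grade -> metastasis):
#' Spearman's rho between each sample's score and the ordinal index of its
#' class. Negative rho means scores decline along the ordering. Invariant
#' to any strictly increasing re-coding of the class ranks.
#'
#' @param scores An `enrichment_scores` tibble (or data frame with
#'   `sample_id`, `score`).
#' @param classes Named character vector (names = sample ids) or data frame
#'   with `sample_id` and `tissue_class`.
#' @param ordered_classes Character vector giving the class order; samples
#'   in other classes are ignored.
#'
#' @return A list with `rho`, `n`, `class_means` (tibble `tissue_class`,
#'   `n`, `mean_score` in the given order).
#' @export
ordinal_trend <- function(scores, classes,
                          ordered_classes = c("normal", "cancer_low_grade",
                                              "cancer_high_grade", "metastasis")) {
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  if (is.data.frame(classes)) {
    stopifnot(all(c("sample_id", "tissue_class") %in% names(classes)))
    cl <- stats::setNames(as.character(classes$tissue_class), classes$sample_id)
  } else {
    cl <- classes
  }
  lab <- cl[scores$sample_id]
  keep <- lab %in% ordered_classes
  x <- scores$score[keep]
  idx <- match(lab[keep], ordered_classes)
  present <- unique(idx)
  if (length(present) < 2) stop("need samples from >=2 ordered classes", call. = FALSE)
  if (length(x) < 3) stop("need >=3 samples in the ordered classes", call. = FALSE)
  rho <- stats::cor(x, idx, method = "spearman")
  class_means <- tibble::tibble(
    tissue_class = ordered_classes,
    n = vapply(seq_along(ordered_classes), function(i) sum(idx == i), numeric(1)),
    mean_score = vapply(seq_along(ordered_classes),
                        function(i) if (any(idx == i)) mean(x[idx == i]) else NA_real_,
                        numeric(1))
  )
  list(rho = rho, n = length(x), class_means = class_means)
}

#' Center scores around zero within each dataset
#'
#' Subtracts each dataset's mean score, so scores from cohorts with
#' different baselines can be drawn on one axis. Idempotent.
#'
#' @param scores Data frame with columns `dataset_id` and `score` (e.g.
#'   row-bound `enrichment_scores` tables with a `dataset_id` column
#'   added), or a single `enrichment_scores` tibble (treated as one
#'   dataset).
#' @return The input with `score` replaced by the within-dataset centered
#'   score.
#' @export
center_per_dataset <- function(scores) {
  stopifnot("score" %in% names(scores))
  if (!"dataset_id" %in% names(scores)) {
    scores$score <- scores$score - mean(scores$score)
    return(scores)
  }
  dplyr::mutate(dplyr::group_by(scores, .data$dataset_id),
                score = .data$score - mean(.data$score)) |>
    dplyr::ungroup()
}

#' Correlation between scores and tumor fraction
#'
#' Plain Pearson correlation of per-sample enrichment scores with the
#' annotated tumor fraction, the standard check that a signature tracks
#' tumor content rather than a technical covariate.
#'
#' @param scores Data frame with `sample_id` and `score`.
#' @param annotations Data frame with `sample_id` and `tumor_fraction`.
#' @return Pearson r (NA if fewer than 3 annotated samples).
#' @export
correlate_tumor_fraction <- function(scores, annotations) {
  stopifnot(all(c("sample_id", "tumor_fraction") %in% names(annotations)))
  tf <- annotations$tumor_fraction[match(scores$sample_id, annotations$sample_id)]
  keep <- !is.na(tf)
  if (sum(keep) < 3) return(NA_real_)
  stats::cor(scores$score[keep], tf[keep])
}
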