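#' Plot a module's CMS across datasets
#'
#' Dot plot of per-dataset CMS values, optionally split by the class filter
#' used, mirroring the standard way module integrity is compared across
#' cohorts.
#'
#' @param ... One or more named tibbles from [evaluate_across_collection()];
#'   the names label the series (e.g. `initial = ..., refined = ...`).
#' @return A ggplot object.
#' @export
plot_cms_across_datasets <- function(...) {
  series <- list(...)
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    names(series) <- paste0("module_", seq_along(series))
  }
  df <- dplyr::bind_rows(lapply(names(series), function(nm) {
    s <- series[[nm]]
    tibble::tibble(dataset_id = s$dataset_id, cms = s$cms, module = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset_id, y = .data$cms,
                                   colour = .data$module)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "dataset", y = "CMS", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Null distribution of the CMS with the observed value
#'
#' @param x A `null_distribution` (see [permutation_null()]).
#' @param object,... Passed through (autoplot interface).
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(x) {
  df <- tidy(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$null_cms)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::labs(x = "null CMS", y = "count") +
    ggplot2::theme_minimal()
  if (!is.na(x$observed)) {
    p <- p + ggplot2::geom_vline(xintercept = x$observed, colour = "red")
  }
  p
}

#' @rdname plot_null_distribution
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, ...) plot_null_distribution(object)

#' Cumulative replacement curve of a refinement
#'
#' Fraction of new (candidate-origin) genes among the top refined ranks,
#' as a function of rank.
#'
#' @param initial,refined [gene_module]s (see [replacement_fraction()]).
#' @return A ggplot object.
#' @export
plot_replacement_curve <- function(initial, refined) {
  rf <- replacement_fraction(initial, refined)
  ggplot2::ggplot(rf$curve, ggplot2::aes(x = .data$rank,
                                         y = .data$cumulative_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "refined rank", y = "cumulative fraction of new genes") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Enrichment-score trajectory across ordered tissue classes
#'
#' Box plot of per-sample scores by class, in the given progression order.
#'
#' @param scores An `enrichment_scores` tibble (or row-bound tables with a
#'   `dataset_id` column).
#' @param classes Data frame with `sample_id`, `tissue_class` (or named
#'   vector).
#' @param ordered_classes Class order for the x axis.
#' @return A ggplot object.
#' @export
plot_score_trajectory <- function(scores, classes,
                                  ordered_classes = c("normal",
                                                      "cancer_low_grade",
                                                      "cancer_high_grade",
                                                      "metastasis")) {
  if (is.data.frame(classes)) {
    cl <- stats::setNames(as.character(classes$tissue_class), classes$sample_id)
  } else {
    cl <- classes
  }
  df <- scores
  df$tissue_class <- cl[df$sample_id]
  df <- df[df$tissue_class %in% ordered_classes, ]
  df$tissue_class <- factor(df$tissue_class, levels = ordered_classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_class, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "ssGSEA score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Hub ranking bar plot
#'
#' @param object A `hub_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hub_ranking
#' @export
autoplot.hub_ranking <- function(object, ...) {
  df <- utils::head(object$table, max(object$n_hubs * 2, 20))
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_degree, y = .data$gene,
                                   fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "mean degree across datasets", y = NULL) +
    ggplot2::theme_minimal()
}
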