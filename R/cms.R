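#' Intra-correlation table of a module in one dataset
#'
#' The full square table of pairwise Pearson correlations between the
#' expression profiles of the module genes present in the dataset, over the
#' chosen samples. For a fully present 150-gene module this is a 150 x 150
#' table (22,500 cells including the diagonal). Genes with zero expression
#' variance over the chosen samples are dropped with a warning and recorded,
#' since Pearson is undefined for them.
#'
#' @param dataset An [expression_dataset].
#' @param module A [gene_module] (or character vector of gene ids).
#' @param samples Sample ids to correlate over, or a class filter via
#'   `class_filter`; default all samples.
#' @param class_filter Convenience alternative to `samples`
#'   (see [samples_in_class()]).
#'
#' @return Object of class `intra_correlation_table`: list with `genes`
#'   (present module genes, module order), `r` (square matrix),
#'   `samples_used`, `missing` (module genes absent from the dataset) and
#'   `dropped` (present genes excluded for zero variance).
#' @export
intra_correlation_table <- function(dataset, module, samples = NULL,
                                    class_filter = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  members <- module_members(module)
  if (is.null(samples)) {
    samples <- if (is.null(class_filter)) dataset$samples
               else samples_in_class(dataset, class_filter)
  }
  if (length(samples) < 3) stop("need >=3 samples, got ", length(samples), call. = FALSE)
  present <- members[members %in% dataset$genes]
  missing <- setdiff(members, present)
  if (length(present) < 2) {
    stop("fewer than 2 module genes present in dataset ", dataset$dataset_id,
         call. = FALSE)
  }
  x <- dataset$values[present, samples, drop = FALSE]
  v <- apply(x, 1, stats::var)
  dropped <- present[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance gene(s) in ", dataset$dataset_id, ": ",
            paste(dropped, collapse = ", "), call. = FALSE)
    present <- setdiff(present, dropped)
    if (length(present) < 2) {
      stop("fewer than 2 module genes with nonzero variance", call. = FALSE)
    }
    x <- x[present, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  structure(
    list(genes = present, r = r, samples_used = length(samples),
         missing = missing, dropped = dropped,
         dataset_id = dataset$dataset_id),
    class = "intra_correlation_table"
  )
}

module_members <- function(module) {
  if (inherits(module, "gene_module")) module$members else as.character(module)
}

#' @export
print.intra_correlation_table <- function(x, ...) {
  cat("<intra_correlation_table> ", x$dataset_id, ": ", length(x$genes), " x ",
      length(x$genes), " = ", length(x$genes)^2, " cells over ", x$samples_used,
      " samples\n", sep = "")
  invisible(x)
}

#' Correlation Module Score (CMS)
#'
#' The mean of all off-diagonal cells of an intra-correlation table: high
#' CMS means the module genes co-vary strongly in that dataset (high module
#' integrity); CMS near zero means the module's internal correlation
#' structure is absent there.
#'
#' @param table An [intra_correlation_table()] result.
#' @return A single number in \[-1, 1\].
#' @export
cms <- function(table) {
  stopifnot(inherits(table, "intra_correlation_table"))
  m <- nrow(table$r)
  if (m < 2) stop("CMS needs at least 2 genes (no off-diagonal cells)", call. = FALSE)
  (sum(table$r) - sum(diag(table$r))) / (m * (m - 1))
}

#' Module Gene Contribution Score (MGCS)
#'
#' One gene's mean Pearson correlation to each of the other module genes:
#' the per-gene decomposition of the CMS (the mean of all MGCS values equals
#' the CMS exactly). A low MGCS flags a gene whose expression profile
#' deviates from the rest of the module.
#'
#' @param table An [intra_correlation_table()] result.
#' @param gene Single gene id present in the table; if omitted, all genes.
#' @return Named numeric vector of MGCS values (single element when `gene`
#'   is given).
#' @export
mgcs <- function(table, gene = NULL) {
  stopifnot(inherits(table, "intra_correlation_table"))
  m <- nrow(table$r)
  if (m < 2) stop("MGCS needs at least 2 genes", call. = FALSE)
  all_mgcs <- (rowSums(table$r) - diag(table$r)) / (m - 1)
  names(all_mgcs) <- table$genes
  if (is.null(gene)) return(all_mgcs)
  if (!gene %in% table$genes) stop("gene not present in table: ", gene, call. = FALSE)
  all_mgcs[gene]
}

#' Evaluate a module's CMS in every dataset of a collection
#'
#' @param collection A [dataset_collection].
#' @param module A [gene_module].
#' @param class_filter Samples to evaluate on (`"all"`, `"cancer"`,
#'   `"normal"`, ... see [samples_in_class()]).
#'
#' @return A tibble with one row per dataset: `dataset_id`, `evaluable`,
#'   `samples_used`, `n_present`, `n_missing`, `cms`, plus list-columns
#'   `mgcs` (named numeric per present gene) and `missing` (character).
#'   Datasets where fewer than 2 module genes are present (or fewer than 3
#'   filtered samples exist) are reported with `evaluable = FALSE` rather
#'   than failing the whole evaluation.
#' @export
evaluate_across_collection <- function(collection, module, class_filter = "all") {
  stopifnot(inherits(collection, "dataset_collection"))
  rows <- lapply(collection$datasets, function(d) {
    res <- tryCatch(
      {
        tab <- intra_correlation_table(d, module, class_filter = class_filter)
        list(ok = TRUE, tab = tab)
      },
      error = function(e) list(ok = FALSE, msg = conditionMessage(e))
    )
    if (!res$ok) {
      return(tibble::tibble(
        dataset_id = d$dataset_id, evaluable = FALSE,
        samples_used = NA_integer_, n_present = NA_integer_,
        n_missing = NA_integer_, cms = NA_real_,
        mgcs = list(NULL), missing = list(character())
      ))
    }
    tab <- res$tab
    tibble::tibble(
      dataset_id = d$dataset_id, evaluable = TRUE,
      samples_used = tab$samples_used,
      n_present = length(tab$genes),
      n_missing = length(tab$missing),
      cms = cms(tab),
      mgcs = list(mgcs(tab)),
      missing = list(tab$missing)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "module") <- module$name
  attr(out, "class_filter") <- class_filter
  out
}
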