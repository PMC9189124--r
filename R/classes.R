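#' Tissue classes recognised in sample annotations
#'
#' Ordered roughly by disease progression; `"cancer"` in a `class_filter`
#' argument expands to `c("cancer_low_grade", "cancer_high_grade")`.
#'
#' @export
tissue_classes <- c(
  "normal", "stroma", "PIN", "cancer_low_grade", "cancer_high_grade",
  "metastasis", "cell_line", "other"
)

#' Construct an expression dataset
#'
#' A light container for one cohort: a genes-by-samples matrix of
#' log-scale expression values plus per-sample annotations. All correlation
#' statistics in the package are taken over the samples of one such dataset.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values must be finite;
#'   the package never re-normalizes them.
#' @param dataset_id Character scalar identifying the cohort.
#' @param annotations Optional tibble/data.frame with columns `sample_id`,
#'   `tissue_class` (one of [tissue_classes]) and optionally `grade_group`
#'   and `tumor_fraction` (in \[0, 1\]). Defaults to all-`other`.
#'
#' @return An object of class `expression_dataset` with elements
#'   `dataset_id`, `genes`, `samples`, `values`, `annotations`.
#' @export
expression_dataset <- function(values, dataset_id = "dataset", annotations = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  check_gene_ids(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ", paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must all be finite", call. = FALSE)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(sample_id = samples, tissue_class = "other")
  }
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("sample_id", "tissue_class") %in% names(annotations))) {
    stop("annotations need columns sample_id, tissue_class", call. = FALSE)
  }
  if (!all(samples %in% annotations$sample_id)) {
    stop("every sample needs an annotation row", call. = FALSE)
  }
  if (!all(annotations$tissue_class %in% tissue_classes)) {
    bad <- setdiff(unique(annotations$tissue_class), tissue_classes)
    stop("unknown tissue_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("tumor_fraction" %in% names(annotations)) {
    tf <- annotations$tumor_fraction
    if (any(!is.na(tf) & (tf < 0 | tf > 1))) stop("tumor_fraction outside [0, 1]", call. = FALSE)
  }
  annotations <- annotations[match(samples, annotations$sample_id), , drop = FALSE]
  structure(
    list(dataset_id = dataset_id, genes = genes, samples = samples,
         values = values, annotations = annotations),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", x$dataset_id, ": ",
      length(x$genes), " genes x ", length(x$samples), " samples\n", sep = "")
  tc <- table(x$annotations$tissue_class)
  cat("  classes:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

check_gene_ids <- function(ids) {
  if (any(!nzchar(ids))) stop("empty gene id", call. = FALSE)
  if (any(grepl("[\t\n]", ids))) stop("gene ids must not contain tab/newline", call. = FALSE)
  invisible(ids)
}

#' Construct a multi-cohort dataset collection
#'
#' @param datasets List of [expression_dataset] objects with distinct ids.
#' @param anchor_id Id of the member paired with metabolite data.
#'
#' @return Object of class `dataset_collection`: a named list of datasets
#'   plus the anchor id.
#' @export
dataset_collection <- function(datasets, anchor_id = NULL) {
  stopifnot(length(datasets) >= 1)
  ok <- vapply(datasets, inherits, logical(1), "expression_dataset")
  if (!all(ok)) stop("all members must be expression_dataset objects", call. = FALSE)
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("dataset ids must be distinct", call. = FALSE)
  names(datasets) <- ids
  if (is.null(anchor_id)) anchor_id <- ids[[1]]
  if (!anchor_id %in% ids) stop("anchor_id is not a member dataset", call. = FALSE)
  structure(list(datasets = datasets, anchor_id = anchor_id),
            class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  cat("<dataset_collection> ", length(x$datasets), " datasets (anchor: ",
      x$anchor_id, ")\n", sep = "")
  for (d in x$datasets) {
    cat("  ", d$dataset_id, ": ", length(d$genes), " genes x ",
        length(d$samples), " samples\n", sep = "")
  }
  invisible(x)
}

#' Anchor dataset of a collection
#' @param collection A [dataset_collection].
#' @return The anchor [expression_dataset].
#' @export
anchor_dataset <- function(collection) {
  stopifnot(inherits(collection, "dataset_collection"))
  collection$datasets[[collection$anchor_id]]
}

#' Construct a metabolite concentration table
#'
#' @param concentrations Nonnegative numeric matrix, metabolites in rows
#'   (rownames), samples in columns (colnames).
#'
#' @return Object of class `metabolite_table`.
#' @export
metabolite_table <- function(concentrations) {
  stopifnot(is.matrix(concentrations), is.numeric(concentrations))
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations))) {
    stop("`concentrations` needs metabolite rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(concentrations))) stop("duplicate metabolite names", call. = FALSE)
  if (anyDuplicated(colnames(concentrations))) stop("duplicate sample ids", call. = FALSE)
  if (!all(is.finite(concentrations))) stop("concentrations must be finite", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  structure(
    list(metabolites = rownames(concentrations),
         samples = colnames(concentrations),
         concentrations = concentrations),
    class = "metabolite_table"
  )
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", length(x$metabolites), " metabolites x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Construct a gene module (ordered gene signature)
#'
#' Rank order encodes importance; `scores` (when given) must be
#' non-increasing along the member order, e.g. the anchor correlations or
#' average MGCS used to select the members.
#'
#' @param members Character vector of unique gene ids, most important first.
#' @param name Module name.
#' @param scores Optional numeric selection scores, same length as members,
#'   non-increasing.
#'
#' @return Object of class `gene_module`.
#' @export
gene_module <- function(members, name = "module", scores = NULL) {
  members <- as.character(members)
  check_gene_ids(members)
  if (anyDuplicated(members)) stop("module members must be unique", call. = FALSE)
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(members))
    if (any(diff(scores) > 1e-12)) {
      stop("scores must be non-increasing in rank order", call. = FALSE)
    }
  }
  structure(list(name = name, members = members, scores = scores),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat("<gene_module> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  head_n <- min(5L, length(x$members))
  cat("  top:", paste(x$members[seq_len(head_n)], collapse = ", "),
      if (length(x$members) > head_n) "...", "\n")
  invisible(x)
}

#' Number of genes in a module
#' @param x A [gene_module].
#' @export
length.gene_module <- function(x) length(x$members)

#' Samples belonging to a tissue-class filter
#'
#' @param dataset An [expression_dataset].
#' @param class_filter `"all"`, `"cancer"` (low- plus high-grade), a single
#'   class from [tissue_classes], or a character vector of classes.
#' @return Character vector of sample ids (dataset order).
#' @export
samples_in_class <- function(dataset, class_filter = "all") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (identical(class_filter, "all")) return(dataset$samples)
  classes <- expand_class_filter(class_filter)
  keep <- dataset$annotations$tissue_class %in% classes
  dataset$samples[keep]
}

expand_class_filter <- function(class_filter) {
  if (identical(class_filter, "cancer")) {
    return(c("cancer_low_grade", "cancer_high_grade"))
  }
  bad <- setdiff(class_filter, tissue_classes)
  if (length(bad)) stop("unknown tissue class in filter: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class_filter
}

#' Subset a dataset to selected samples and/or genes
#'
#' @param dataset An [expression_dataset].
#' @param samples Sample ids to keep (default all).
#' @param genes Gene ids to keep (default all).
#' @return A new [expression_dataset].
#' @export
subset_dataset <- function(dataset, samples = NULL, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(samples)) samples <- dataset$samples
  if (is.null(genes)) genes <- dataset$genes
  missing_s <- setdiff(samples, dataset$samples)
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "), call. = FALSE)
  genes <- intersect(genes, dataset$genes)
  expression_dataset(
    dataset$values[genes, samples, drop = FALSE],
    dataset_id = dataset$dataset_id,
    annotations = dataset$annotations[match(samples, dataset$annotations$sample_id), ,
                                      drop = FALSE]
  )
}
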