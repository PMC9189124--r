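#' Read a gene-by-sample expression table
#'
#' Supported dialects: plain TSV/CSV with gene ids in the first column and
#' sample ids in the header, and GCT 1.2 (a `#1.2` line, a dims line, then a
#' header with `NAME`, `Description` and sample ids).
#'
#' Duplicate gene ids are an error here; parse with
#' [read_expression_rows()] + [collapse_duplicate_genes()] when the platform
#' maps several probes to one gene.
#'
#' @param path File path.
#' @param dialect `"tsv"`, `"csv"` or `"gct"`.
#' @param dataset_id Dataset id to attach; defaults to the file name sans
#'   extension.
#' @param annotations Optional per-sample annotation table (see
#'   [expression_dataset]).
#'
#' @return An [expression_dataset].
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv", "gct"),
                                  dataset_id = NULL, annotations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- read_expression_rows(path, dialect)
  mat <- raw_rows_to_matrix(raw, allow_duplicates = FALSE)
  expression_dataset(mat, dataset_id = dataset_id, annotations = annotations)
}

#' Read an expression table without the uniqueness check
#'
#' Returns the raw parsed rows (gene id + numeric matrix) so that duplicate
#' probe/gene rows can be collapsed by [collapse_duplicate_genes()].
#'
#' @inheritParams read_expression_table
#' @return A list with `gene` (character) and `values` (numeric matrix with
#'   sample colnames; rows parallel `gene`).
#' @export
read_expression_rows <- function(path, dialect = c("tsv", "csv", "gct")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path)
  if (dialect == "gct") {
    if (length(lines) < 3 || !startsWith(lines[[1]], "#1.2")) {
      stop("not a GCT 1.2 file (missing #1.2 header)", call. = FALSE)
    }
    dims <- as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]][1:2])
    header <- strsplit(lines[[3]], "\t", fixed = TRUE)[[1]]
    samples <- header[-(1:2)]
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    n_field <- lengths(fields)
    if (any(n_field != length(header))) stop("ragged GCT rows", call. = FALSE)
    gene <- vapply(fields, `[[`, character(1), 1L)
    vals <- parse_numeric_cells(fields, drop = 2L, path = path)
    if (nrow(vals) != dims[1] || length(samples) != dims[2]) {
      stop("GCT declared dims (", dims[1], "x", dims[2], ") do not match parsed dims (",
           nrow(vals), "x", length(samples), ")", call. = FALSE)
    }
  } else {
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2) stop("expression table needs a header and >=1 row", call. = FALSE)
    header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
    samples <- header[-1]
    fields <- strsplit(lines[-1], sep, fixed = TRUE)
    n_field <- lengths(fields)
    if (any(n_field != length(header))) stop("ragged rows in ", path, call. = FALSE)
    gene <- vapply(fields, `[[`, character(1), 1L)
    vals <- parse_numeric_cells(fields, drop = 1L, path = path)
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids in ", path, call. = FALSE)
  colnames(vals) <- samples
  list(gene = gene, values = vals)
}

parse_numeric_cells <- function(fields, drop, path) {
  ncol <- length(fields[[1]]) - drop
  cells <- unlist(lapply(fields, function(f) f[-seq_len(drop)]), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) stop("non-numeric or missing cells in ", path, call. = FALSE)
  matrix(vals, nrow = length(fields), ncol = ncol, byrow = TRUE)
}

raw_rows_to_matrix <- function(raw, allow_duplicates = FALSE) {
  if (!allow_duplicates && anyDuplicated(raw$gene)) {
    dup <- unique(raw$gene[duplicated(raw$gene)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  mat <- raw$values
  rownames(mat) <- raw$gene
  mat
}

#' Collapse duplicated gene rows of a parsed expression table
#'
#' Platforms measuring several probes per gene yield repeated gene ids; the
#' matrices used downstream are per unique gene. `highest_mean` keeps, for
#' each gene, the row with the largest mean expression across samples
#' (first occurrence wins exact ties).
#'
#' @param raw Output of [read_expression_rows()].
#' @param policy `"highest_mean"` or `"error"`.
#' @inheritParams read_expression_table
#' @return An [expression_dataset] with unique gene rows.
#' @export
collapse_duplicate_genes <- function(raw, policy = c("highest_mean", "error"),
                                     dataset_id = "dataset", annotations = NULL) {
  policy <- match.arg(policy)
  if (policy == "error") {
    mat <- raw_rows_to_matrix(raw, allow_duplicates = FALSE)
    return(expression_dataset(mat, dataset_id, annotations))
  }
  means <- rowMeans(raw$values)
  ord <- order(raw$gene, -means)
  keep <- ord[!duplicated(raw$gene[ord])]
  keep <- sort(keep)  # preserve original row order among the winners
  mat <- raw$values[keep, , drop = FALSE]
  rownames(mat) <- raw$gene[keep]
  expression_dataset(mat, dataset_id, annotations)
}

#' Write an expression dataset as TSV
#'
#' Emits a header `gene<TAB>sample...` and one row per gene, full-precision
#' (round-trip safe) numbers, '.' decimal mark.
#'
#' @param dataset An [expression_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", dataset$samples), collapse = "\t"), con)
  body <- vapply(seq_along(dataset$genes), function(i) {
    paste(c(dataset$genes[[i]],
            format_full(dataset$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

format_full <- function(x) {
  # shortest representation that round-trips a double
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Union or shared gene universe of a collection
#'
#' @param collection A [dataset_collection].
#' @param mode `"union"` (every gene in any dataset, first-seen order) or
#'   `"shared"` (genes present in every dataset, order of the first dataset).
#' @return Character vector of gene ids.
#' @export
gene_universe <- function(collection, mode = c("union", "shared")) {
  mode <- match.arg(mode)
  gene_lists <- lapply(collection$datasets, function(d) d$genes)
  if (mode == "union") {
    unique(unlist(gene_lists, use.names = FALSE))
  } else {
    Reduce(intersect, gene_lists)
  }
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then the member gene ids, all
#' tab-separated. Member order is preserved (it encodes rank).
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of [gene_module] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  mods <- lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields", call. = FALSE)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      stop("duplicate member in gene set '", f[[1]], "'", call. = FALSE)
    }
    gene_module(members, name = f[[1]])
  })
  names(mods) <- vapply(mods, function(m) m$name, character(1))
  mods
}

#' @rdname read_gmt
#' @param modules A [gene_module] or list of them.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @return `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(modules, path, descriptions = NULL) {
  if (inherits(modules, "gene_module")) modules <- list(modules)
  if (is.null(descriptions)) descriptions <- rep("na", length(modules))
  stopifnot(length(descriptions) == length(modules))
  lines <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    paste(c(m$name, descriptions[[i]], m$members), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a per-sample metabolite concentration table
#'
#' TSV with metabolites in rows (first column holds the metabolite name)
#' and sample ids in the header. Concentrations must be nonnegative.
#'
#' @param path File path.
#' @return A [metabolite_table].
#' @export
read_metabolite_table <- function(path) {
  raw <- read_expression_rows(path, "tsv")
  if (anyDuplicated(raw$gene)) stop("duplicate metabolite names", call. = FALSE)
  mat <- raw$values
  rownames(mat) <- raw$gene
  metabolite_table(mat)
}

#' Write a metabolite table as TSV
#' @param table A [metabolite_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(table, path) {
  stopifnot(inherits(table, "metabolite_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("metabolite", table$samples), collapse = "\t"), con)
  body <- vapply(seq_along(table$metabolites), function(i) {
    paste(c(table$metabolites[[i]], format_full(table$concentrations[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' TSV with columns `sample_id`, `tissue_class`, optionally `grade_group`
#' and `tumor_fraction`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @return `write_annotations()`: `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
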