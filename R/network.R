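#' Top-k absolute-correlation network of a module in one dataset
#'
#' Module genes present in the dataset become nodes; each node keeps
#' directed edges to the `k` other genes with the largest absolute Pearson
#' correlation to it over the chosen samples (all n-1 when the module is
#' small), ties broken lexicographically by target gene id. Keeping only the
#' strongest outgoing links per node sparsifies the graph while letting
#' central genes accumulate many incoming links.
#'
#' @param dataset An [expression_dataset].
#' @param module A [gene_module] or character vector.
#' @param k Outgoing-link budget per node (default 20).
#' @param samples Sample ids, or use `class_filter`.
#' @param class_filter Tissue-class filter (default `"cancer"`).
#'
#' @return Object of class `module_network`: list with `dataset_id`,
#'   `nodes`, `edges` (tibble `source`, `target`, `abs_r`) and `k`.
#' @export
build_topk_network <- function(dataset, module, k = 20, samples = NULL,
                               class_filter = "cancer") {
  tab <- intra_correlation_table(dataset, module, samples = samples,
                                 class_filter = class_filter)
  nodes <- tab$genes
  n <- length(nodes)
  a <- abs(tab$r)
  edges <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-a[i, others], nodes[others])]
    keep <- ord[seq_len(min(k, n - 1))]
    tibble::tibble(source = nodes[i], target = nodes[keep], abs_r = a[i, keep])
  })
  structure(
    list(dataset_id = dataset$dataset_id, nodes = nodes,
         edges = dplyr::bind_rows(edges), k = k),
    class = "module_network"
  )
}

#' @export
print.module_network <- function(x, ...) {
  cat("<module_network> ", x$dataset_id, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Node degrees of a module network
#'
#' @param network A [build_topk_network()] result.
#' @param mode `"distinct"` (default): number of distinct adjacent nodes in
#'   the union of in- and out-links, a reciprocal pair counted once.
#'   `"in_out"`: in-degree plus out-degree, reciprocal links counted twice.
#' @return Named numeric vector of degrees over the network's nodes.
#' @export
network_degree <- function(network, mode = c("distinct", "in_out")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "module_network"))
  deg <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  e <- network$edges
  if (mode == "distinct") {
    und <- unique(tibble::tibble(
      a = pmin(e$source, e$target),
      b = pmax(e$source, e$target)
    ))
    t1 <- table(und$a); t2 <- table(und$b)
    deg[names(t1)] <- deg[names(t1)] + as.numeric(t1)
    deg[names(t2)] <- deg[names(t2)] + as.numeric(t2)
  } else {
    t_out <- table(e$source); t_in <- table(e$target)
    deg[names(t_out)] <- deg[names(t_out)] + as.numeric(t_out)
    deg[names(t_in)] <- deg[names(t_in)] + as.numeric(t_in)
  }
  deg
}

#' Cross-dataset hub ranking of module genes
#'
#' Builds the per-dataset top-k network for every dataset of the
#' collection, computes node degrees, and ranks genes by mean degree across
#' datasets. By default a gene absent from a dataset contributes degree 0
#' to its mean, so hubs must be both central and broadly measured;
#' `absent = "exclude"` averages over the datasets where the gene is
#' present instead.
#'
#' @param collection A [dataset_collection].
#' @param module A [gene_module] or character vector.
#' @param k Outgoing-link budget per node (default 20).
#' @param n_hubs Number of top hub genes to flag (default 10).
#' @param class_filter Samples used (default `"cancer"`).
#' @param degree_mode See [network_degree()].
#' @param absent `"zero"` (default) or `"exclude"`.
#'
#' @return Object of class `hub_ranking`: list with `table` (tibble
#'   `gene`, `mean_degree`, `n_datasets_present`, `rank`, `is_hub`),
#'   `hubs` (character vector of the `n_hubs` top genes) and `networks`
#'   (list of per-dataset `module_network`s).
#' @export
hub_ranking <- function(collection, module, k = 20, n_hubs = 10,
                        class_filter = "cancer",
                        degree_mode = "distinct", absent = c("zero", "exclude")) {
  absent <- match.arg(absent)
  members <- module_members(module)
  networks <- list()
  for (d in collection$datasets) {
    net <- tryCatch(
      build_topk_network(d, module, k = k, class_filter = class_filter),
      error = function(e) NULL
    )
    if (!is.null(net)) networks[[d$dataset_id]] <- net
  }
  if (!length(networks)) stop("module network not constructible in any dataset",
                              call. = FALSE)
  deg_mat <- matrix(if (absent == "zero") 0 else NA_real_,
                    nrow = length(members), ncol = length(networks),
                    dimnames = list(members, names(networks)))
  for (id in names(networks)) {
    deg <- network_degree(networks[[id]], mode = degree_mode)
    deg_mat[names(deg), id] <- deg
  }
  mean_degree <- rowMeans(deg_mat, na.rm = TRUE)
  mean_degree[is.nan(mean_degree)] <- 0
  present_n <- vapply(members, function(g) {
    sum(vapply(networks, function(nw) g %in% nw$nodes, logical(1)))
  }, numeric(1))
  ord <- order(-mean_degree, members)
  tbl <- tibble::tibble(
    gene = members[ord],
    mean_degree = unname(mean_degree[ord]),
    n_datasets_present = unname(present_n[ord]),
    rank = seq_along(ord)
  )
  n_hubs <- min(n_hubs, nrow(tbl))
  tbl$is_hub <- tbl$rank <= n_hubs
  structure(list(table = tbl, hubs = tbl$gene[seq_len(n_hubs)],
                 networks = networks, k = k, n_hubs = n_hubs),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat("<hub_ranking> top ", x$n_hubs, " hubs over ", length(x$networks),
      " dataset networks (k = ", x$k, ")\n  ", sep = "")
  cat(paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Write per-dataset edge lists of a hub ranking
#'
#' One TSV per dataset network with columns `source`, `target`, `abs_r`.
#'
#' @param ranking A [hub_ranking()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_edge_lists <- function(ranking, dir) {
  stopifnot(inherits(ranking, "hub_ranking"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(ranking$networks)) {
    e <- ranking$networks[[id]]$edges
    path <- file.path(dir, paste0("edges_", id, ".tsv"))
    con <- file(path, open = "wb")
    writeLines(paste(c("source", "target", "abs_r"), collapse = "\t"), con)
    writeLines(paste(e$source, e$target, format_full(e$abs_r), sep = "\t"), con)
    close(con)
  }
  invisible(dir)
}
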