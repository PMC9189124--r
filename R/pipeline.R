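#' Run the full signature pipeline and write its artifacts
#'
#' simulate -> derive -> refine -> score -> network, end to end on synthetic
#' data: generates a multi-cohort collection, derives the initial
#' anchor-correlated module, refines it across the cohorts, scores every
#' sample of every cohort with ssGSEA for the refined module, ranks hub
#' genes, and writes all artifacts to `out_dir`. Fully deterministic given
#' `(config, seed)`: two runs produce byte-identical files.
#'
#' Files written: `initial.gmt`, `refined.gmt`, `refine_report.tsv`
#' (per-dataset CMS of both modules on cancer and normal samples),
#' `scores.tsv` (per-sample ssGSEA of the refined module), `hubs.tsv`
#' (mean-degree hub ranking), `metabolites.tsv`, `annotations.tsv`, and
#' one `edges_<dataset>.tsv` per cohort network.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving the whole run.
#' @param config A [generator_config()].
#' @param k Module size (default: the config's planted-module size).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param network_k Outgoing-link budget per network node (default 20).
#' @param n_hubs Number of hub genes (default 10).
#'
#' @return Invisibly, a list with `simulation`, `run` (the `refine_run`),
#'   `scores`, `hubs` and `files`.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = generator_config(),
                         k = config$module_size, alpha = 0.25,
                         network_k = 20, n_hubs = 10) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_collection(config, seed = seed)
  run <- refine(sim$collection, sim$metabolites, c("citrate", "spermine"), k = k)

  scores <- dplyr::bind_rows(lapply(sim$collection$datasets, function(d) {
    s <- ssgsea_dataset(d, run$result$refined, alpha = alpha)
    s$dataset_id <- d$dataset_id
    s
  }))
  hubs <- hub_ranking(sim$collection, run$result$refined, k = network_k,
                      n_hubs = n_hubs)

  files <- c(
    initial = file.path(out_dir, "initial.gmt"),
    refined = file.path(out_dir, "refined.gmt"),
    report = file.path(out_dir, "refine_report.tsv"),
    scores = file.path(out_dir, "scores.tsv"),
    hubs = file.path(out_dir, "hubs.tsv"),
    metabolites = file.path(out_dir, "metabolites.tsv"),
    annotations = file.path(out_dir, "annotations.tsv")
  )
  write_gmt(run$initial, files[["initial"]])
  write_gmt(run$result$refined, files[["refined"]])
  write_tsv_plain(run$report, files[["report"]])
  write_tsv_plain(scores[, c("dataset_id", "sample_id", "module", "score",
                             "universe_size", "mode", "alpha")],
                  files[["scores"]])
  write_tsv_plain(hubs$table, files[["hubs"]])
  write_metabolite_table(sim$metabolites, files[["metabolites"]])
  write_tsv_plain(sim$truth$samples[, c("dataset_id", "sample_id", "tissue_class")],
                  files[["annotations"]])
  write_edge_lists(hubs, out_dir)

  invisible(list(simulation = sim, run = run, scores = scores, hubs = hubs,
                 files = files))
}

# Deterministic TSV writer: LF line endings, '.'-decimal, round-trip-safe
# doubles, no quoting.
write_tsv_plain <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- format_full(col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
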