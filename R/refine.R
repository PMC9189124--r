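#' Stage 1: per-dataset MGCS of the initial module, with missing-gene constants
#'
#' For every dataset, builds the intra-correlation table over the initial
#' module genes present there (on the class-filtered samples) and records
#' each gene's MGCS. A module gene absent from a dataset's platform cannot
#' be scored, so it receives that dataset's *missing-gene constant*, defined
#' as 0.5 x the dataset's module CMS — half the typical module-internal
#' correlation, a deliberately conservative stand-in. Datasets where fewer
#' than two module genes are present are excluded with a warning.
#'
#' @param collection A [dataset_collection].
#' @param initial The initial [gene_module].
#' @param class_filter Samples used throughout refinement (default
#'   `"cancer"`).
#'
#' @return A list with `mgcs_table` (genes x datasets matrix, constants
#'   substituted for absences), `constants` (named per-dataset vector),
#'   `cms` (named per-dataset vector) and `missing` (named list of absent
#'   genes per dataset).
#' @export
refine_stage1 <- function(collection, initial, class_filter = "cancer") {
  stopifnot(inherits(collection, "dataset_collection"),
            inherits(initial, "gene_module"))
  members <- initial$members
  cols <- list(); constants <- c(); cms_vec <- c(); missing <- list()
  for (d in collection$datasets) {
    tab <- tryCatch(
      intra_correlation_table(d, initial, class_filter = class_filter),
      error = function(e) NULL
    )
    if (is.null(tab)) {
      warning("dataset ", d$dataset_id, " excluded from refinement (module not evaluable)",
              call. = FALSE)
      next
    }
    cms_d <- cms(tab)
    const_d <- 0.5 * cms_d
    g_mgcs <- mgcs(tab)
    col <- rep(const_d, length(members))
    names(col) <- members
    col[names(g_mgcs)] <- g_mgcs
    cols[[d$dataset_id]] <- col
    constants[[d$dataset_id]] <- const_d
    cms_vec[[d$dataset_id]] <- cms_d
    missing[[d$dataset_id]] <- setdiff(members, tab$genes)
  }
  if (!length(cols)) stop("initial module not evaluable in any dataset", call. = FALSE)
  mgcs_table <- do.call(cbind, cols)
  list(mgcs_table = mgcs_table, constants = constants, cms = cms_vec,
       missing = missing)
}

#' Stage 2: correlate every candidate gene with the module-average profile
#'
#' For each dataset, the module-average profile is the elementwise mean of
#' the expression profiles of the initial-module genes present there.
#' Every gene of the union universe is then correlated (Pearson) with that
#' average profile; genes absent from the dataset — and candidates whose
#' expression has zero variance — take the dataset's missing-gene constant.
#' Initial-module genes are retained in the table here; Stage 3 excludes
#' them before ranking candidates.
#'
#' @inheritParams refine_stage1
#' @param stage1 Output of [refine_stage1()].
#'
#' @return A list with `cor_table` (universe genes x datasets matrix) and
#'   `universe` (union gene universe, first-seen order).
#' @export
refine_stage2 <- function(collection, initial, stage1, class_filter = "cancer") {
  universe <- gene_universe(collection, "union")
  datasets_used <- colnames(stage1$mgcs_table)
  cols <- list()
  for (id in datasets_used) {
    d <- collection$datasets[[id]]
    samples <- samples_in_class(d, class_filter)
    present_init <- intersect(initial$members, d$genes)
    avg_profile <- colMeans(d$values[present_init, samples, drop = FALSE])
    col <- rep(stage1$constants[[id]], length(universe))
    names(col) <- universe
    in_d <- universe[universe %in% d$genes]
    if (stats::sd(avg_profile) == 0) {
      warning("module-average profile constant in ", id,
              "; all candidates take the missing-gene constant", call. = FALSE)
    } else {
      r <- pearson_to_vector(d$values[in_d, samples, drop = FALSE], avg_profile)
      n_zero_var <- sum(is.na(r))
      if (n_zero_var > 0) {
        warning(n_zero_var, " zero-variance candidate(s) in ", id,
                " set to the missing-gene constant", call. = FALSE)
        r[is.na(r)] <- stage1$constants[[id]]
      }
      col[in_d] <- r
    }
    cols[[id]] <- col
  }
  list(cor_table = do.call(cbind, cols), universe = universe)
}

#' Stage 3: nominate candidates, re-rank the combined table, select the
#' refined module
#'
#' Initial-module genes are excluded from the Stage-2 correlation table;
#' the `k` candidates with the highest average correlation across datasets
#' are nominated. Each nominated candidate then gets a per-dataset MGCS:
#' its mean correlation to the initial-module genes present in that dataset
#' (the missing-gene constant where the candidate is absent). The candidate
#' MGCS table is combined with the Stage-1 initial MGCS table into a
#' 2k-gene table; the `k` genes with the highest average MGCS across
#' datasets form the refined module. All ties break lexicographically by
#' gene id.
#'
#' @inheritParams refine_stage2
#' @param stage2 Output of [refine_stage2()].
#' @param k Refined module size (default: size of the initial module).
#'
#' @return Object of class `refinement_result`: list with `refined`
#'   ([gene_module], scores = average MGCS), `combined_ranking` (tibble of
#'   all 2k genes: `gene`, `origin`, `avg_mgcs`, `rank`), `candidates`
#'   (the k nominated gene ids), `replaced_count` and `replaced_fraction`.
#' @export
refine_stage3 <- function(collection, initial, stage1, stage2,
                          k = NULL, class_filter = "cancer") {
  if (is.null(k)) k <- length(initial$members)
  if (k > length(initial$members)) stop("k exceeds the initial module size", call. = FALSE)
  cand_table <- stage2$cor_table[!rownames(stage2$cor_table) %in% initial$members, ,
                                 drop = FALSE]
  if (k > nrow(cand_table)) stop("k exceeds the number of candidate genes", call. = FALSE)
  avg_cor <- rowMeans(cand_table)
  ord <- order(-avg_cor, rownames(cand_table))
  candidates <- rownames(cand_table)[ord[seq_len(k)]]

  datasets_used <- colnames(stage1$mgcs_table)
  cand_mgcs <- matrix(NA_real_, nrow = k, ncol = length(datasets_used),
                      dimnames = list(candidates, datasets_used))
  for (id in datasets_used) {
    d <- collection$datasets[[id]]
    samples <- samples_in_class(d, class_filter)
    present_init <- intersect(initial$members, d$genes)
    col <- rep(stage1$constants[[id]], k)
    names(col) <- candidates
    in_d <- candidates[candidates %in% d$genes]
    if (length(in_d) && length(present_init)) {
      r <- stats::cor(t(d$values[in_d, samples, drop = FALSE]),
                      t(d$values[present_init, samples, drop = FALSE]))
      row_mean <- rowMeans(r)
      bad <- is.na(row_mean)
      if (any(bad)) row_mean[bad] <- stage1$constants[[id]]
      col[in_d] <- row_mean
    }
    cand_mgcs[, id] <- col
  }

  combine_rank_select(stage1$mgcs_table, cand_mgcs, k, candidates = candidates)
}

# Combine the initial and candidate MGCS tables (2k rows), rank by the
# unweighted average MGCS across datasets (ties lexicographic by gene id)
# and keep the top k as the refined module.
combine_rank_select <- function(initial_mgcs, cand_mgcs, k, candidates = NULL) {
  combined <- rbind(initial_mgcs, cand_mgcs)
  origin <- c(rep("initial", nrow(initial_mgcs)),
              rep("candidate", nrow(cand_mgcs)))
  avg_mgcs <- rowMeans(combined)
  ord2 <- order(-avg_mgcs, rownames(combined))
  ranking <- tibble::tibble(
    gene = rownames(combined)[ord2],
    origin = origin[ord2],
    avg_mgcs = avg_mgcs[ord2],
    rank = seq_along(ord2)
  )
  top <- ranking[seq_len(k), ]
  refined <- gene_module(top$gene, name = "refined", scores = top$avg_mgcs)
  replaced <- sum(!refined$members %in% rownames(initial_mgcs))
  structure(
    list(refined = refined, combined_ranking = ranking,
         candidates = if (is.null(candidates)) rownames(cand_mgcs) else candidates,
         candidate_mgcs = cand_mgcs,
         replaced_count = replaced, replaced_fraction = replaced / k),
    class = "refinement_result"
  )
}

#' @export
print.refinement_result <- function(x, ...) {
  k <- length(x$refined$members)
  cat("<refinement_result> ", k, "-gene refined module; ", x$replaced_count,
      " of ", k, " genes replaced (", round(100 * x$replaced_fraction, 1),
      "%)\n", sep = "")
  invisible(x)
}

#' Full anchor-to-refined-signature orchestration
#'
#' Derives the anchor metabolite profile and the initial top-k module from
#' the anchor dataset, runs refinement Stages 1-3 across the collection
#' (anchor included by default; the refinement itself uses only the
#' class-filtered samples), and evaluates the CMS of the initial and
#' refined modules on both cancer- and normal-class samples of every
#' dataset.
#'
#' @param collection A [dataset_collection].
#' @param metab A [metabolite_table] for the anchor dataset.
#' @param metabolites Metabolite names averaged into the anchor profile.
#' @param k Module size (default 150).
#' @param class_filter Sample class used for signature derivation and
#'   refinement (default `"cancer"`).
#' @param include_anchor Include the anchor dataset in Stages 1-3
#'   (default TRUE; set FALSE to refine on the other cohorts only).
#' @param n_perm If > 0, also computes the shuffled-profile permutation
#'   null and lognormal p for the initial module on the anchor dataset.
#' @param seed Seed for the permutation null.
#'
#' @return Object of class `refine_run`: list with `initial`
#'   ([gene_module]), `profile`, `correlations`, `result`
#'   (`refinement_result`), `report` (tibble: per dataset, CMS of
#'   initial/refined module on cancer and normal samples plus missing-gene
#'   counts) and `null` (a `null_distribution` or NULL).
#' @export
refine <- function(collection, metab, metabolites, k = 150,
                   class_filter = "cancer", include_anchor = TRUE,
                   n_perm = 0, seed = 1) {
  init <- derive_initial_module(collection, metab, metabolites, k = k,
                                class_filter = class_filter)
  refine_collection <- if (include_anchor) collection else {
    others <- collection$datasets[names(collection$datasets) != collection$anchor_id]
    dataset_collection(others, anchor_id = others[[1]]$dataset_id)
  }
  s1 <- refine_stage1(refine_collection, init$module, class_filter)
  s2 <- refine_stage2(refine_collection, init$module, s1, class_filter)
  s3 <- refine_stage3(refine_collection, init$module, s1, s2, k = k,
                      class_filter = class_filter)

  report <- build_refine_report(collection, init$module, s3$refined)

  null <- NULL
  if (n_perm > 0) {
    anchor <- anchor_dataset(collection)
    samples <- intersect(samples_in_class(anchor, class_filter), metab$samples)
    obs_tab <- intra_correlation_table(anchor, init$module, samples = samples)
    null <- permutation_null(anchor, init$profile, samples = samples, k = k,
                             n_perm = n_perm, seed = seed,
                             observed_cms = cms(obs_tab))
  }
  structure(
    list(initial = init$module, profile = init$profile,
         correlations = init$correlations, stage1 = s1, result = s3,
         report = report, null = null),
    class = "refine_run"
  )
}

build_refine_report <- function(collection, initial, refined) {
  eval_one <- function(module, filt) {
    evaluate_across_collection(collection, module, class_filter = filt)
  }
  ic <- eval_one(initial, "cancer"); rc <- eval_one(refined, "cancer")
  im <- eval_one(initial, "normal"); rm_ <- eval_one(refined, "normal")
  tibble::tibble(
    dataset_id = ic$dataset_id,
    cms_initial_cancer = ic$cms,
    cms_refined_cancer = rc$cms,
    cms_initial_normal = im$cms,
    cms_refined_normal = rm_$cms,
    n_missing_initial = ic$n_missing,
    n_missing_refined = rc$n_missing
  )
}

#' @export
print.refine_run <- function(x, ...) {
  print(x$result)
  cat("  datasets evaluated:", nrow(x$report), "\n")
  if (!is.null(x$null) && !is.na(x$null$p)) {
    cat("  initial-module lognormal p (anchor):", format(x$null$p, digits = 3), "\n")
  }
  invisible(x)
}

#' How many initial genes were replaced during refinement
#'
#' @param initial,refined [gene_module]s of the same nominal size.
#' @return A list with `count` (genes of `refined` absent from `initial`),
#'   `fraction` (count / size of refined) and `curve`, a tibble giving at
#'   each refined rank 1..k the cumulative fraction of new genes among the
#'   top-ranked members so far.
#' @export
replacement_fraction <- function(initial, refined) {
  stopifnot(length(initial$members) >= 1, length(refined$members) >= 1)
  is_new <- !refined$members %in% initial$members
  k <- length(refined$members)
  curve <- tibble::tibble(
    rank = seq_len(k),
    cumulative_new = cumsum(is_new),
    cumulative_fraction = cumsum(is_new) / seq_len(k)
  )
  list(count = sum(is_new), fraction = sum(is_new) / k, curve = curve)
}
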