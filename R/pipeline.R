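#' Pipeline configuration
#'
#' Validated, typed configuration for [run_pipeline()]. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param qc A [qc_thresholds()] object.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @param scale_factor Optional normalization scale-factor override (default:
#'   median nCounts).
#' @param n_hvg Number of variable genes (default 200).
#' @param n_pcs Number of principal components (default 30, capped at `n_hvg`).
#' @param k_neighbors Clustering graph neighbourhood size (default 20).
#' @param resolution Community-detection resolution (default 1).
#' @param doublet List: `enabled`, `n_sim_multiplier` (simulated doublets per
#'   observed cell, default 2), `k_neighbors` (NULL = `round(0.5*sqrt(n))`),
#'   `n_pcs`, `strategy` (`"fixed_quantile"`/`"fixed_threshold"`), `param`
#'   (default quantile 0.05, the expected doublet rate).
#' @param panel A [marker_panel()].
#' @param score List: `n_bins`, `n_ctrl` for [module_score()].
#' @param margin Cluster-annotation score margin.
#' @param de List: `min_pct`, `logfc_min`, `alpha`, `p_adjust`
#'   (`"bh"`/`"bonferroni"`), `universe` (`"hvg"` or `"all"`).
#' @param probe_genes Probe genes for the fraction report.
#' @param seed Single global seed; stages derive their own seeds from it.
#' @param verbose Log stage progress to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            mito_prefix = "MT-",
                            scale_factor = NULL,
                            n_hvg = 200,
                            n_pcs = 30,
                            k_neighbors = 20,
                            resolution = 1.0,
                            doublet = list(),
                            panel = marker_panel(),
                            score = list(),
                            margin = 0.05,
                            de = list(),
                            probe_genes = c("ID1", "ID2", "ID3", "MYOG", "PAX7", "OSR1"),
                            seed = 1L,
                            verbose = FALSE) {
  merge_opts <- function(defaults, given, what) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("unknown ", what, " option(s): ", paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  doublet <- merge_opts(list(enabled = TRUE, n_sim_multiplier = 2,
                             k_neighbors = NULL, n_pcs = 30,
                             strategy = "fixed_quantile", param = 0.05),
                        doublet, "doublet")
  score <- merge_opts(list(n_bins = NULL, n_ctrl = 100), score, "score")
  de <- merge_opts(list(min_pct = 0.1, logfc_min = 0.25, alpha = 0.05,
                        p_adjust = "bh", universe = "hvg"), de, "de")
  if (!de$universe %in% c("hvg", "all")) abort("de$universe must be 'hvg' or 'all'")
  if (!inherits(qc, "qc_thresholds")) abort("qc must be a qc_thresholds object")
  if (!inherits(panel, "marker_panel")) abort("panel must be a marker_panel object")
  structure(list(qc = qc, mito_prefix = mito_prefix, scale_factor = scale_factor,
                 n_hvg = n_hvg, n_pcs = n_pcs, k_neighbors = k_neighbors,
                 resolution = resolution, doublet = doublet, panel = panel,
                 score = score, margin = margin, de = de,
                 probe_genes = probe_genes, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full identity-calling pipeline
#'
#' Executes the fixed stage order: QC filtering, doublet scoring and removal,
#' log normalization, variable-gene selection, PCA, graph clustering, cluster
#' annotation, dual-cell calling, four-way identity assignment, CT/M module
#' scores, differential statistics, and the fraction report. All randomness is
#' driven by per-stage seeds derived from the single configured seed, so two
#' runs with the same configuration are identical.
#'
#' @param dataset A `limb_dataset` (from [simulate_counts()] or
#'   [read_dataset()]) or a directory path readable by [read_dataset()].
#' @param config A [pipeline_config()].
#' @return A `limb_result` list: `qc`, `doublet_scores`, `clusters`,
#'   `cluster_classes`, `cell_table` (per-cell tibble with QC stats, cluster,
#'   doublet score, dual flag, identity and CT/M scores), `scores`,
#'   `fractions`, `markers`, `dual_de`, `id_fraction_tests`, `norm`,
#'   `embedding`, and a reproducibility `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  v <- config$verbose
  stage <- function(name, expr) {
    .log_stage(v, "stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  qc <- stage("qc_filter", qc_filter(dataset$counts, config$qc, config$mito_prefix))
  .log_stage(v, "  kept ", ncol(qc$counts), "/", ncol(dataset$counts), " cells")

  doublet_scores <- NULL
  counts <- qc$counts
  if (isTRUE(config$doublet$enabled)) {
    doublet_scores <- stage("doublet_filter", {
      sim <- simulate_synthetic_doublets(
        counts, n_sim = config$doublet$n_sim_multiplier * ncol(counts),
        seed = derive_seed(config$seed, "doublet_sim")
      )
      sc <- score_doublets(counts, sim, k_neighbors = config$doublet$k_neighbors,
                           n_pcs = config$doublet$n_pcs,
                           seed = derive_seed(config$seed, "doublet_embed"))
      call_doublets(sc, strategy = config$doublet$strategy,
                    param = config$doublet$param)
    })
    counts <- counts[, !doublet_scores$is_doublet_call, drop = FALSE]
    .log_stage(v, "  removed ", sum(doublet_scores$is_doublet_call), " doublet calls")
  }

  norm <- stage("log_normalize", log_normalize(counts, config$scale_factor))
  hvg <- stage("select_hvg", select_hvg(norm, n_hvg = min(config$n_hvg, nrow(counts))))
  emb <- stage("embed_pca", embed_pca(norm, hvg, n_pcs = min(config$n_pcs, length(hvg))))
  clusters <- stage("cluster_cells",
                    cluster_cells(emb, k_neighbors = config$k_neighbors,
                                  resolution = config$resolution,
                                  seed = derive_seed(config$seed, "cluster")))
  scores <- stage("module_score",
                  score_table(norm, config$panel, n_bins = config$score$n_bins,
                              n_ctrl = config$score$n_ctrl, seed = config$seed))
  classes <- stage("annotate_clusters",
                   annotate_clusters(norm, clusters, config$panel,
                                     margin = config$margin, scores = scores))
  dual <- stage("call_dual", call_dual(norm, config$panel))
  labels <- stage("assign_identity", assign_identity(clusters, classes, dual))

  universe <- if (config$de$universe == "hvg") {
    unique(c(hvg, config$panel$ct_genes, config$panel$m_genes, config$probe_genes))
  } else rownames(counts)
  markers <- stage("find_markers",
                   find_markers(norm, clusters, genes = universe,
                                min_pct = config$de$min_pct,
                                logfc_min = config$de$logfc_min,
                                alpha_adj = config$de$alpha,
                                p_adjust = config$de$p_adjust))
  dual_de <- stage("de_dual_vs_union",
                   de_dual_vs_union(norm, labels, config$panel, genes = universe,
                                    alpha_adj = config$de$alpha,
                                    p_adjust = config$de$p_adjust))
  id_probe <- intersect(config$probe_genes, c("ID1", "ID2", "ID3"))
  id_tests <- NULL
  if (length(id_probe) > 0 && any(labels$identity == "CT_M")) {
    id_tests <- stage("fraction_expressing_compare", {
      pairs <- list(c("CT_M", "CT"), c("CT_M", "M"))
      purrr::map_dfr(pairs, function(pr) {
        if (!all(pr %in% labels$identity)) return(NULL)
        fraction_expressing_compare(norm, id_probe, labels, pr[1], pr[2]) |>
          dplyr::mutate(group_a = pr[1], group_b = pr[2])
      })
    })
  }
  fractions <- stage("identity_fraction_report",
                     identity_fraction_report(labels, norm, config$panel,
                                              config$probe_genes))

  cell_table <- qc$report |>
    dplyr::left_join(
      if (is.null(doublet_scores)) {
        tibble::tibble(barcode = character(), raw_score = numeric(),
                       adjusted_score = numeric(), is_doublet_call = logical())
      } else tibble::as_tibble(doublet_scores),
      by = "barcode"
    ) |>
    dplyr::left_join(labels, by = "barcode") |>
    dplyr::left_join(dual, by = "barcode") |>
    dplyr::left_join(tibble::as_tibble(scores), by = "barcode")

  manifest <- list(
    package_version = as.character(utils::packageVersion("limbdual")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_cells_input = ncol(dataset$counts),
    n_cells_retained = ncol(counts),
    n_genes = nrow(counts),
    scale_factor = norm$scale_factor,
    n_clusters = dplyr::n_distinct(clusters$cluster)
  )
  structure(list(qc = qc, doublet_scores = doublet_scores, clusters = clusters,
                 cluster_classes = classes, cell_table = cell_table,
                 scores = scores, dual = dual, labels = labels,
                 fractions = fractions, markers = markers, dual_de = dual_de,
                 id_fraction_tests = id_tests, norm = norm, embedding = emb,
                 hvg = hvg, manifest = manifest, truth = dataset$truth),
            class = "limb_result")
}

#' @export
print.limb_result <- function(x, ...) {
  cat("<limb_result> ", x$manifest$n_cells_retained, " cells retained of ",
      x$manifest$n_cells_input, ", ", x$manifest$n_clusters, " clusters\n", sep = "")
  print(x$fractions$identity_percent)
  invisible(x)
}

#' Parameter-recovery benchmark over a grid of planted fractions
#'
#' For every combination of planted dual fraction and doublet rate, and for
#' each of `n_seeds` seeds, simulates a dataset, runs the pipeline and records
#' the recovered CT_M percentage, the planted percentage (transitional share
#' of singlets), the doublet-score AUROC against truth, the transitional
#' false-call rate at the doublet stage, and the adjusted Rand index between
#' clusters and true populations (transitional cells and doublets excluded).
#'
#' @param base_sim A [sim_config()] used as template.
#' @param base_config A [pipeline_config()] used as template.
#' @param dual_fractions,doublet_rates Numeric grids.
#' @param n_seeds Seeds per grid point (>= 1; >= 3 for meaningful spread).
#' @return A `recovery_benchmark` list: `runs` (one row per run) and `summary`
#'   (mean and SD per grid point).
#' @export
recovery_benchmark <- function(base_sim = sim_config(), base_config = pipeline_config(),
                               dual_fractions = c(0, 0.04),
                               doublet_rates = 0.05, n_seeds = 3) {
  grid <- tidyr::expand_grid(dual_fraction = dual_fractions,
                             doublet_rate = doublet_rates,
                             rep = seq_len(n_seeds))
  runs <- purrr::pmap_dfr(grid, function(dual_fraction, doublet_rate, rep) {
    seed <- derive_seed(base_sim$seed, 100L + rep)
    sc <- base_sim
    sc$dual_fraction <- dual_fraction
    sc$doublet_rate <- doublet_rate
    sc$seed <- seed
    # rebuild through the constructor so invariants are revalidated
    sc <- sim_config(n_cells = sc$n_cells, n_genes_total = sc$n_genes_total,
                     dual_fraction = dual_fraction, doublet_rate = doublet_rate,
                     biphasic_mode = sc$biphasic_mode,
                     nb_dispersion = sc$nb_dispersion, libsize_mu = sc$libsize_mu,
                     libsize_sigma = sc$libsize_sigma,
                     mito_gene_count = sc$mito_gene_count,
                     mito_high_fraction = sc$mito_high_fraction,
                     panel = sc$panel, seed = seed)
    cfg <- base_config
    cfg$seed <- seed
    ds <- simulate_counts(sc)
    res <- run_pipeline(ds, cfg)
    m <- evaluate_against_truth(res, ds$truth)
    tibble::tibble(dual_fraction = dual_fraction, doublet_rate = doublet_rate,
                   rep = rep, seed = seed, !!!m)
  })
  summary <- runs |>
    dplyr::group_by(.data$dual_fraction, .data$doublet_rate) |>
    dplyr::summarise(dplyr::across(
      c("recovered_ctm_pct", "doublet_auroc", "transitional_doublet_call_rate",
        "cluster_ari"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~stats::sd(.x, na.rm = TRUE))
    ), .groups = "drop")
  structure(list(runs = runs, summary = summary), class = "recovery_benchmark")
}

#' Score a pipeline result against simulator ground truth
#'
#' @param result A `limb_result`.
#' @param truth The simulator ground-truth tibble.
#' @return One-row tibble: `recovered_ctm_pct`, `planted_ctm_pct`,
#'   `doublet_auroc`, `transitional_doublet_call_rate`, `cluster_ari`.
#' @export
evaluate_against_truth <- function(result, truth) {
  labels <- result$labels
  recovered <- 100 * mean(labels$identity == "CT_M")
  singlets <- truth[!truth$is_doublet, ]
  planted <- 100 * mean(singlets$population == "TRANSITIONAL")

  auc <- NA_real_
  trans_rate <- NA_real_
  if (!is.null(result$doublet_scores)) {
    sc <- dplyr::inner_join(tibble::as_tibble(result$doublet_scores),
                            truth[, c("barcode", "population", "is_doublet")],
                            by = "barcode")
    if (any(sc$is_doublet) && any(!sc$is_doublet)) {
      auc <- auroc(sc$adjusted_score, sc$is_doublet)
    }
    trans <- sc$population == "TRANSITIONAL" & !sc$is_doublet
    if (any(trans, na.rm = TRUE)) {
      trans_rate <- mean(sc$is_doublet_call[which(trans)])
    }
  }

  eval_cells <- dplyr::inner_join(
    result$clusters,
    truth[!truth$is_doublet & truth$population != "TRANSITIONAL",
          c("barcode", "population")],
    by = "barcode"
  )
  ari <- if (nrow(eval_cells) > 1) {
    mclust::adjustedRandIndex(eval_cells$cluster, eval_cells$population)
  } else NA_real_

  tibble::tibble(recovered_ctm_pct = recovered, planted_ctm_pct = planted,
                 doublet_auroc = auc, transitional_doublet_call_rate = trans_rate,
                 cluster_ari = ari)
}
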