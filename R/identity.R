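#' Call dual CT/M cells by marker co-expression
#'
#' A cell is dual iff it co-expresses (log-normalized value strictly > 0) at
#' least one CT marker and at least one muscle marker. No other genes are
#' consulted.
#'
#' @param norm A `normalized_matrix` from [log_normalize()].
#' @param panel A [marker_panel()]; every panel gene must be present.
#' @return Tibble (`barcode`, `is_dual`).
#' @export
call_dual <- function(norm, panel = marker_panel()) {
  if (!inherits(norm, "normalized_matrix")) abort("norm must be a normalized_matrix")
  genes <- rownames(norm$values)
  .assert_genes_present(c(panel$ct_genes, panel$m_genes), genes, "panel gene")
  ct_pos <- .col_any_positive(norm$values, genes %in% panel$ct_genes)
  m_pos <- .col_any_positive(norm$values, genes %in% panel$m_genes)
  tibble::tibble(barcode = colnames(norm$values), is_dual = unname(ct_pos & m_pos))
}

#' Bin-controlled gene module score
#'
#' The corrected average expression of a gene set: genes are ranked by mean
#' expression across cells and cut into `n_bins` equal-frequency bins; for each
#' set gene, `n_ctrl` control genes (capped at bin occupancy) are sampled
#' without replacement from its bin, excluding all set genes; the per-cell
#' score is the mean expression of the set genes minus the mean expression of
#' all sampled controls. Adding a constant to every value of every gene leaves
#' scores unchanged.
#'
#' @param norm A `normalized_matrix`, or a plain genes x cells numeric matrix.
#' @param gene_set Character vector of set genes (non-empty, strict subset of
#'   all genes so that controls exist).
#' @param n_bins Number of equal-frequency expression bins. The default
#'   (`NULL`) uses 25 bins, reduced on small gene panels so that each bin holds
#'   about `n_ctrl` genes (`min(25, floor(n_genes / 100))`, at least 1): with
#'   only a handful of genes per bin the control average is a noisy, biased
#'   background estimate and the nominal control count cannot be honoured.
#' @param n_ctrl Controls sampled per set gene (default 100, capped at bin
#'   occupancy).
#' @param seed Integer seed for control sampling; fixed seed gives identical
#'   scores.
#' @param exclude_from_controls Genes ineligible as controls (default: the set
#'   genes themselves). [score_table()] additionally excludes the reciprocal
#'   marker set: at desk scale a bin holds few genes, and markers of the
#'   opposite identity would otherwise enter the "background" of their
#'   counterpart's score.
#' @return Named numeric vector of per-cell scores.
#' @examples
#' m <- matrix(c(2, 0, 1, 1), nrow = 4,
#'             dimnames = list(c("g1", "g2", "g3", "g4"), "cell1"))
#' module_score(m, "g1", n_bins = 1, n_ctrl = 3, seed = 1)  # 2 - 2/3 = 4/3
#' @export
module_score <- function(norm, gene_set, n_bins = NULL, n_ctrl = 100, seed = 1L,
                         exclude_from_controls = gene_set) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  genes <- rownames(values)
  if (length(gene_set) == 0) abort("gene_set must be non-empty")
  .assert_genes_present(gene_set, genes)
  if (length(setdiff(genes, gene_set)) == 0) {
    abort("gene_set must be a strict subset of the genes: no controls exist")
  }
  exclude_from_controls <- union(exclude_from_controls, gene_set)
  mu <- Matrix::rowSums(values) / ncol(values)
  n_bins <- n_bins %||% max(1, min(25, floor(length(genes) / 100)))
  n_bins <- min(n_bins, length(genes))
  bin <- dplyr::ntile(rank(mu, ties.method = "first"), n_bins)
  names(bin) <- genes

  set.seed(seed)
  controls <- character(0)
  for (g in gene_set) {
    pool <- genes[bin == bin[[g]] & !(genes %in% exclude_from_controls)]
    if (length(pool) == 0) {
      abort(paste0("no eligible control genes in the expression bin of ", g))
    }
    take <- min(n_ctrl, length(pool))
    controls <- c(controls, sample(pool, take, replace = FALSE))
  }
  set_mean <- Matrix::colSums(values[gene_set, , drop = FALSE]) / length(gene_set)
  # a control drawn for two set genes is counted once per draw
  ctrl_mean <- Matrix::colSums(values[controls, , drop = FALSE]) / length(controls)
  setNames(as.numeric(set_mean - ctrl_mean), colnames(values))
}

#' CT and M module scores for every cell
#'
#' Convenience wrapper computing the CT score and M score of each cell with
#' [module_score()] under per-module derived seeds.
#'
#' @inheritParams module_score
#' @param panel A [marker_panel()].
#' @param seed Global seed; the two module draws use seeds derived from it.
#' @return A `score_table` tibble (`barcode`, `ct_score`, `m_score`) with the
#'   scoring parameters as attributes.
#' @export
score_table <- function(norm, panel = marker_panel(), n_bins = NULL, n_ctrl = 100,
                        seed = 1L) {
  all_panel <- c(panel$ct_genes, panel$m_genes)
  out <- tibble::tibble(
    barcode = colnames(norm$values),
    ct_score = unname(module_score(norm, panel$ct_genes, n_bins, n_ctrl,
                                   seed = derive_seed(seed, "module_ct"),
                                   exclude_from_controls = all_panel)),
    m_score = unname(module_score(norm, panel$m_genes, n_bins, n_ctrl,
                                  seed = derive_seed(seed, "module_m"),
                                  exclude_from_controls = all_panel))
  )
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  class(out) <- c("score_table", class(out))
  out
}

#' Classify clusters as CT, M or Other by mean module-score difference
#'
#' A cluster is CT when its mean CT score exceeds its mean M score by more
#' than `margin`, M in the reverse case, and Other when the absolute
#' difference is within `margin`.
#'
#' @param norm A `normalized_matrix`.
#' @param clusters A `cluster_assignment` from [cluster_cells()].
#' @param panel A [marker_panel()].
#' @param margin Score-difference margin (default 0.05).
#' @param scores Optional precomputed [score_table()]; computed if missing.
#' @param seed Seed for the module-score draw when `scores` is missing.
#' @return Tibble (`cluster`, `class`, `mean_ct_score`, `mean_m_score`).
#' @export
annotate_clusters <- function(norm, clusters, panel = marker_panel(), margin = 0.05,
                              scores = NULL, seed = 1L) {
  if (dplyr::n_distinct(clusters$cluster) < 1) abort("need at least one cluster")
  scores <- scores %||% score_table(norm, panel, seed = seed)
  dplyr::inner_join(clusters, scores, by = "barcode") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_ct_score = mean(.data$ct_score),
                     mean_m_score = mean(.data$m_score), .groups = "drop") |>
    dplyr::mutate(
      diff = .data$mean_ct_score - .data$mean_m_score,
      class = dplyr::case_when(
        .data$diff > margin ~ "CT",
        .data$diff < -margin ~ "M",
        TRUE ~ "OTHER"
      )
    ) |>
    dplyr::select("cluster", "class", "mean_ct_score", "mean_m_score")
}

#' Assign the four-way CT / CT_M / M / Other identity
#'
#' Dual cells are labelled `CT_M` regardless of their cluster; every other
#' cell inherits its cluster's class (CT, M or OTHER). The labels form an
#' exhaustive, disjoint partition of the cells.
#'
#' @param clusters A `cluster_assignment`.
#' @param cluster_classes Tibble from [annotate_clusters()] (columns `cluster`,
#'   `class`).
#' @param dual Tibble from [call_dual()] (columns `barcode`, `is_dual`).
#' @return Tibble (`barcode`, `cluster`, `identity`) with `identity` a factor
#'   with levels CT, CT_M, M, OTHER.
#' @export
assign_identity <- function(clusters, cluster_classes, dual) {
  out <- dplyr::left_join(clusters, cluster_classes[, c("cluster", "class")],
                          by = "cluster") |>
    dplyr::left_join(dual, by = "barcode")
  if (any(is.na(out$class))) abort("every cell must belong to a classified cluster")
  if (any(is.na(out$is_dual))) abort("every cell needs a dual call")
  out |>
    dplyr::mutate(identity = factor(ifelse(.data$is_dual, "CT_M", .data$class),
                                    levels = c("CT", "CT_M", "M", "OTHER"))) |>
    dplyr::select("barcode", "cluster", "identity")
}

#' Identity and marker-positivity fraction report
#'
#' Quantifies (i) the percentage of cells carrying each identity, (ii) among
#' cells expressing each probe gene, the percentage that are dual (e.g. the
#' share of MYOG+ myoblasts with a dual signature), and (iii) the percentage
#' of dual cells expressing each panel and probe gene. All percentages are on
#' the 0-100 scale, with all retained cells as the identity denominator.
#'
#' @param labels Tibble from [assign_identity()] (columns `barcode`, `identity`).
#' @param norm A `normalized_matrix` covering the same cells.
#' @param panel A [marker_panel()].
#' @param probe_genes Genes for the dual-among-positive quantification.
#' @return A `fraction_report`: list of tibbles `identity_percent`,
#'   `dual_among_positive`, `marker_fraction_in_dual`.
#' @export
identity_fraction_report <- function(labels, norm,
                                     panel = marker_panel(),
                                     probe_genes = c("ID1", "ID2", "ID3", "MYOG",
                                                     "PAX7", "OSR1")) {
  values <- norm$values
  if (!setequal(labels$barcode, colnames(values))) {
    abort("labels must cover exactly the cells of the normalized matrix")
  }
  .assert_genes_present(probe_genes, rownames(values), "probe gene")
  labels <- labels[match(colnames(values), labels$barcode), ]
  n <- nrow(labels)
  identity_percent <- labels |>
    dplyr::count(.data$identity, .drop = FALSE) |>
    dplyr::mutate(percent = 100 * .data$n / !!n) |>
    dplyr::select("identity", "n", "percent")

  is_dual <- labels$identity == "CT_M"
  dual_among_positive <- purrr::map_dfr(probe_genes, function(g) {
    pos <- as.vector(values[g, ] > 0)
    tibble::tibble(gene = g, n_positive = sum(pos),
                   percent_dual = if (sum(pos) > 0) 100 * sum(pos & is_dual) / sum(pos) else NA_real_)
  })

  all_genes <- unique(c(panel$ct_genes, panel$m_genes, probe_genes))
  marker_fraction_in_dual <- purrr::map_dfr(all_genes, function(g) {
    expr <- as.vector(values[g, is_dual] > 0)
    tibble::tibble(gene = g, n_dual = sum(is_dual),
                   percent_expressing = if (sum(is_dual) > 0) 100 * mean(expr) else NA_real_)
  })

  structure(list(identity_percent = identity_percent,
                 dual_among_positive = dual_among_positive,
                 marker_fraction_in_dual = marker_fraction_in_dual),
            class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat("<fraction_report>\n")
  print(x$identity_percent)
  invisible(x)
}

#' Serialize a fraction report
#'
#' Writes the three report tables as TSV files and a combined JSON summary
#' (keys `identity_percent`, `dual_among_positive`, `marker_fraction_in_dual`).
#'
#' @param report A `fraction_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fraction_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report)) {
    readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(lapply(unclass(report), identity),
                       file.path(dir, "fraction_report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
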