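# Marker discovery and identity-contrast differential expression, built on
# the package's own Wilcoxon / BH implementations.

# Accept group labels as a tibble (barcode + one label column) or a named
# vector, aligned to the matrix columns.
.resolve_groups <- function(labels, barcodes) {
  if (is.data.frame(labels)) {
    candidates <- c("group", "identity", "cluster")
    lab_col <- candidates[candidates %in% names(labels)][1]
    if (is.na(lab_col)) abort("labels must contain a 'group', 'identity' or 'cluster' column")
    v <- setNames(as.character(labels[[lab_col]]), labels$barcode)
  } else {
    v <- setNames(as.character(labels), names(labels))
  }
  if (!all(barcodes %in% names(v))) abort("labels must cover every cell")
  unname(v[barcodes])
}

.de_one_contrast <- function(dense, in_idx, out_idx, min_pct, logfc_min, eps = 1e-9) {
  pct_in <- rowMeans(dense[, in_idx, drop = FALSE] > 0)
  pct_out <- rowMeans(dense[, out_idx, drop = FALSE] > 0)
  mean_in <- rowMeans(expm1(dense[, in_idx, drop = FALSE]))
  mean_out <- rowMeans(expm1(dense[, out_idx, drop = FALSE]))
  log_fc <- log((mean_in + eps) / (mean_out + eps))
  keep <- (pct_in >= min_pct | pct_out >= min_pct) & abs(log_fc) >= logfc_min
  genes <- rownames(dense)[keep]
  p_raw <- vapply(which(keep), function(i) {
    wilcoxon_rank_sum(dense[i, in_idx], dense[i, out_idx])$p
  }, numeric(1))
  tibble::tibble(gene = genes, log_fc = unname(log_fc[keep]), p_raw = unname(p_raw),
                 pct_in = unname(pct_in[keep]), pct_out = unname(pct_out[keep]))
}

#' One-vs-rest marker discovery
#'
#' For each group, tests every candidate gene with the Wilcoxon rank-sum test
#' against all remaining cells. Genes are pre-filtered to those detected in at
#' least `min_pct` of either side and with `|log_fc| >= logfc_min`, where
#' `log_fc` is the natural-log ratio of back-transformed group means
#' (`ln((mean(expm1(in)) + 1e-9) / (mean(expm1(out)) + 1e-9))`). P-values are
#' adjusted within each group across all its tests.
#'
#' @param norm A `normalized_matrix`.
#' @param groups Per-cell group labels: tibble with `barcode` plus a `group`,
#'   `identity` or `cluster` column, or a named vector.
#' @param genes Candidate gene universe (default: all genes).
#' @param min_pct Minimum detection fraction on at least one side (default 0.1).
#' @param logfc_min Minimum absolute log fold change (default 0.25).
#' @param alpha_adj Adjusted-p significance cut-off (default 0.05).
#' @param p_adjust `"bh"` (default) or `"bonferroni"`.
#' @return A `de_table` tibble (`gene`, `group`, `log_fc`, `p_raw`, `p_adj`,
#'   `pct_in`, `pct_out`, `direction`, `significant`), sorted by group, then
#'   adjusted p, then |log_fc|, then gene. Groups with fewer than 3 cells are
#'   skipped with a warning.
#' @export
find_markers <- function(norm, groups, genes = NULL, min_pct = 0.1,
                         logfc_min = 0.25, alpha_adj = 0.05,
                         p_adjust = c("bh", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  values <- norm$values
  g <- .resolve_groups(groups, colnames(values))
  if (dplyr::n_distinct(g) < 2) abort("need at least 2 groups")
  genes <- genes %||% rownames(values)
  .assert_genes_present(genes, rownames(values))
  dense <- as.matrix(values[genes, , drop = FALSE])

  out <- purrr::map_dfr(sort(unique(g)), function(grp) {
    in_idx <- which(g == grp)
    if (length(in_idx) < 3) {
      warn(paste0("group '", grp, "' has fewer than 3 cells; skipped"))
      return(NULL)
    }
    res <- .de_one_contrast(dense, in_idx, which(g != grp), min_pct, logfc_min)
    if (nrow(res) == 0) return(NULL)
    res$group <- grp
    res$p_adj <- adjust_p(res$p_raw, p_adjust)
    res
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene = character(), group = character(),
                          log_fc = numeric(), p_raw = numeric(), p_adj = numeric(),
                          pct_in = numeric(), pct_out = numeric())
  }
  out <- out |>
    dplyr::mutate(direction = ifelse(.data$log_fc >= 0, "up", "down"),
                  significant = .data$p_adj < alpha_adj) |>
    dplyr::select("gene", "group", "log_fc", "p_raw", "p_adj", "pct_in",
                  "pct_out", "direction", "significant") |>
    dplyr::arrange(.data$group, .data$p_adj, dplyr::desc(abs(.data$log_fc)), .data$gene)
  class(out) <- c("de_table", class(out))
  out
}

#' Top markers per group
#'
#' @param de A `de_table` from [find_markers()].
#' @param n Markers per group (default 10).
#' @param direction `"up"` (default), `"down"` or `"both"`.
#' @return The filtered `de_table` rows (significant only), `n` per group.
#' @export
top_markers <- function(de, n = 10, direction = c("up", "down", "both")) {
  dir_arg <- match.arg(direction)
  de |>
    dplyr::filter(.data$significant,
                  dir_arg == "both" | .data$direction == dir_arg) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}

#' Differential expression of dual cells against the combined CT and M pool
#'
#' Tests CT_M cells against the union of CT and M cells per gene (Wilcoxon with
#' BH adjustment) and summarises the bi-phasic behaviour of the marker panel:
#' for each panel gene, direction and significance against the combined pool
#' and against the gene's own reference population (CT cells for CT markers,
#' M cells for muscle markers).
#'
#' @param norm A `normalized_matrix`.
#' @param labels Identity labels from [assign_identity()] (tibble with
#'   `barcode`, `identity`).
#' @param panel A [marker_panel()].
#' @param genes Gene universe for the main contrast (default: all genes; panel
#'   genes are always included).
#' @param alpha_adj Adjusted-p cut-off (default 0.05).
#' @param p_adjust `"bh"` or `"bonferroni"`.
#' @return A `dual_de` list: `table` (`de_table` of CT_M vs CT+M), `biphasic`
#'   (per panel gene summary) and `status` (`"ok"` or `"no dual cells"`).
#' @export
de_dual_vs_union <- function(norm, labels, panel = marker_panel(), genes = NULL,
                             alpha_adj = 0.05, p_adjust = c("bh", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  values <- norm$values
  id <- .resolve_groups(labels, colnames(values))
  dual_idx <- which(id == "CT_M")
  empty <- tibble::tibble(gene = character(), log_fc = numeric(),
                          p_raw = numeric(), p_adj = numeric())
  if (length(dual_idx) == 0) {
    return(structure(list(table = empty, biphasic = empty, status = "no dual cells"),
                     class = "dual_de"))
  }
  union_idx <- which(id %in% c("CT", "M"))
  if (length(union_idx) == 0) abort("no CT or M cells to compare against")
  genes <- unique(c(genes %||% rownames(values), panel$ct_genes, panel$m_genes))
  .assert_genes_present(genes, rownames(values))
  dense <- as.matrix(values[genes, , drop = FALSE])

  tab <- .de_one_contrast(dense, dual_idx, union_idx, min_pct = 0, logfc_min = 0)
  tab$p_adj <- adjust_p(tab$p_raw, p_adjust)
  tab <- tab |>
    dplyr::mutate(group = "CT_M", direction = ifelse(.data$log_fc >= 0, "up", "down"),
                  significant = .data$p_adj < alpha_adj) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(abs(.data$log_fc)), .data$gene)

  panel_genes <- c(panel$ct_genes, panel$m_genes)
  side <- c(rep("ct", length(panel$ct_genes)), rep("m", length(panel$m_genes)))
  own <- purrr::map_dfr(seq_along(panel_genes), function(i) {
    ref_idx <- which(id == if (side[i] == "ct") "CT" else "M")
    if (length(ref_idx) == 0) {
      return(tibble::tibble(gene = panel_genes[i], log_fc_vs_own = NA_real_,
                            p_raw_vs_own = NA_real_))
    }
    r <- .de_one_contrast(dense[panel_genes[i], , drop = FALSE], dual_idx, ref_idx,
                          min_pct = 0, logfc_min = 0)
    tibble::tibble(gene = panel_genes[i], log_fc_vs_own = r$log_fc,
                   p_raw_vs_own = r$p_raw)
  })
  own$p_adj_vs_own <- ifelse(is.na(own$p_raw_vs_own), NA_real_,
                             adjust_p(ifelse(is.na(own$p_raw_vs_own), 1, own$p_raw_vs_own),
                                      p_adjust))
  biphasic <- tibble::tibble(gene = panel_genes, side = side) |>
    dplyr::left_join(tab[, c("gene", "log_fc", "p_adj", "significant")], by = "gene") |>
    dplyr::rename(log_fc_vs_union = "log_fc", p_adj_vs_union = "p_adj",
                  significant_vs_union = "significant") |>
    dplyr::left_join(own, by = "gene") |>
    dplyr::mutate(
      direction_vs_union = ifelse(.data$log_fc_vs_union >= 0, "up", "down"),
      direction_vs_own = ifelse(.data$log_fc_vs_own >= 0, "up", "down")
    )
  structure(list(table = tab, biphasic = biphasic, status = "ok"), class = "dual_de")
}

#' @export
print.dual_de <- function(x, ...) {
  cat("<dual_de> status:", x$status, "-", nrow(x$table), "genes tested\n")
  if (x$status == "ok") print(x$biphasic)
  invisible(x)
}

#' Compare expressing fractions between two identity groups
#'
#' For each gene of a set (and pooled: expressing at least one gene of the
#' set), compares the fraction of expressing cells (value > 0) between two
#' groups with the two-sided Fisher exact test.
#'
#' @param norm A `normalized_matrix`.
#' @param gene_set Genes to compare (e.g. ID1/ID2/ID3).
#' @param labels Identity labels (tibble with `barcode` and `identity`/`group`).
#' @param group_a,group_b Labels of the two groups.
#' @return Tibble (`gene`, `n_a`, `n_b`, `frac_a`, `frac_b`, `p`); the last row
#'   has `gene = "pooled"`.
#' @export
fraction_expressing_compare <- function(norm, gene_set, labels, group_a, group_b) {
  values <- norm$values
  .assert_genes_present(gene_set, rownames(values))
  id <- .resolve_groups(labels, colnames(values))
  ia <- which(id == group_a)
  ib <- which(id == group_b)
  if (length(ia) == 0 || length(ib) == 0) abort("both groups must be non-empty")
  sub <- values[gene_set, , drop = FALSE] > 0
  one <- function(expr_a, expr_b, gene) {
    tab <- matrix(c(sum(expr_a), sum(expr_b),
                    sum(!expr_a), sum(!expr_b)), 2, byrow = TRUE)
    tibble::tibble(gene = gene, n_a = length(expr_a), n_b = length(expr_b),
                   frac_a = mean(expr_a), frac_b = mean(expr_b),
                   p = fisher_exact_2x2(tab))
  }
  per_gene <- purrr::map_dfr(gene_set, function(g) {
    one(as.vector(sub[g, ia]), as.vector(sub[g, ib]), g)
  })
  pooled_a <- Matrix::colSums(sub[, ia, drop = FALSE]) > 0
  pooled_b <- Matrix::colSums(sub[, ib, drop = FALSE]) > 0
  dplyr::bind_rows(per_gene, one(as.vector(pooled_a), as.vector(pooled_b), "pooled"))
}
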