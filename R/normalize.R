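#' Median-scaled log normalization
#'
#' Scales each cell to a common library size and log-transforms:
#' `value(g, c) = ln(1 + count(g, c) / total(c) * s)`, with the scale factor
#' `s` defaulting to the median of per-cell totals. The transform is strictly
#' monotone within a cell and maps zeros to zeros, so sparsity is preserved.
#'
#' @param counts Sparse genes x cells count matrix, a `limb_dataset`, or a
#'   `qc_result`.
#' @param scale_factor Optional fixed scale factor; default median nCounts.
#' @return A `normalized_matrix`: list with `values` (sparse genes x cells) and
#'   `scale_factor`.
#' @examples
#' m <- Matrix::Matrix(matrix(c(2, 0, 8, 10, 0, 10), nrow = 3,
#'                     dimnames = list(c("a", "b", "c"), c("c1", "c2"))), sparse = TRUE)
#' log_normalize(m, scale_factor = 20)$values["a", "c1"]  # ln(1 + 2/10*20) = ln(5)
#' @export
log_normalize <- function(counts, scale_factor = NULL) {
  if (inherits(counts, "limb_dataset") || inherits(counts, "qc_result")) counts <- counts$counts
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    abort("cells with zero total counts present; run qc_filter() first")
  }
  s <- scale_factor %||% as.numeric(median(totals))
  values <- counts
  per_entry_total <- rep.int(totals, diff(counts@p))
  values@x <- log1p(counts@x / per_entry_total * s)
  structure(list(values = values, scale_factor = s), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, scale factor ", format(x$scale_factor), "\n", sep = "")
  invisible(x)
}

#' Select highly variable genes by binned standardized dispersion
#'
#' Ranks genes by the variance of their normalized values, standardized within
#' equal-frequency bins of mean expression (z-score of variance within each of
#' `n_bins` bins), and returns the top `n_hvg`. Genes with zero variance are
#' never selected while any gene varies. The procedure is deterministic.
#'
#' @param norm A `normalized_matrix` from [log_normalize()].
#' @param n_hvg Number of genes to return.
#' @param n_bins Number of equal-frequency mean-expression bins.
#' @return Character vector of gene names, ordered by decreasing standardized
#'   dispersion.
#' @export
select_hvg <- function(norm, n_hvg = 200, n_bins = 20) {
  if (!inherits(norm, "normalized_matrix")) abort("norm must be a normalized_matrix")
  if (n_hvg <= 0) abort("n_hvg must be > 0")
  v <- norm$values
  if (n_hvg > nrow(v)) abort("n_hvg exceeds the number of genes")
  n <- ncol(v)
  mu <- Matrix::rowSums(v) / n
  ex2 <- Matrix::rowSums(v^2) / n
  vr <- pmax(ex2 - mu^2, 0) * n / max(n - 1, 1)

  stats <- tibble::tibble(gene = rownames(v), idx = seq_len(nrow(v)), mu = mu, vr = vr) |>
    dplyr::mutate(bin = dplyr::ntile(.data$mu, min(n_bins, nrow(v)))) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(
      disp = ifelse(rep(dplyr::n() > 1 && stats::sd(.data$vr) > 0, dplyr::n()),
                    (.data$vr - mean(.data$vr)) / stats::sd(.data$vr), 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$vr > 0) |>
    dplyr::arrange(dplyr::desc(.data$disp), .data$idx)
  head(stats$gene, n_hvg)
}
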