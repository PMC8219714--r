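#' Quality-control thresholds
#'
#' Per-cell QC cut-offs on the number of detected genes (nFeatures), total
#' molecule count (nCounts) and mitochondrial expression fraction (pMito).
#' `max_counts = NULL` applies the 99.5th percentile of nCounts at filter time,
#' a rule standing in for manual outlier inspection on an nFeature-vs-nCount
#' scatter.
#'
#' @param min_features,max_features Bounds on detected genes per cell.
#' @param min_counts,max_counts Bounds on total molecules per cell.
#' @param max_pmito Maximum mitochondrial fraction, in `[0, 1]`.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_features = 200, max_features = Inf,
                          min_counts = 500, max_counts = NULL,
                          max_pmito = 0.1) {
  if (min_features > max_features) abort("min_features > max_features")
  if (!is.null(max_counts) && min_counts > max_counts) abort("min_counts > max_counts")
  if (!.is_prop(max_pmito)) abort("max_pmito must be in [0, 1]")
  structure(list(min_features = min_features, max_features = max_features,
                 min_counts = min_counts, max_counts = max_counts,
                 max_pmito = max_pmito), class = "qc_thresholds")
}

#' Filter cells on classical quality-control statistics
#'
#' Computes per-cell nFeatures, nCounts and pMito (fraction of counts on genes
#' whose name starts with `mito_prefix`; defined as 0 for a cell with zero
#' total counts, which the `min_counts` rule then removes) and drops every cell
#' violating any threshold.
#'
#' @param counts Sparse genes x cells count matrix, or a `limb_dataset`.
#' @param thresholds A [qc_thresholds()] object.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return A `qc_result`: list with `counts` (filtered matrix), `report`
#'   (per-cell tibble: `barcode`, `n_features`, `n_counts`, `p_mito`, `kept`
#'   and one logical column per violated rule) and `tally` (removal counts per
#'   rule; cells may be tallied under several rules).
#' @examples
#' ds <- simulate_counts(sim_config(n_cells = c(CT = 60, M = 60),
#'                                  dual_fraction = 0, doublet_rate = 0, seed = 2))
#' qc <- qc_filter(ds)
#' qc$tally
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(), mito_prefix = "MT-") {
  if (inherits(counts, "limb_dataset")) counts <- counts$counts
  n_counts <- unname(Matrix::colSums(counts))
  n_features <- unname(Matrix::colSums(counts > 0))
  mito_genes <- startsWith(rownames(counts), mito_prefix)
  mito_counts <- if (any(mito_genes)) Matrix::colSums(counts[mito_genes, , drop = FALSE]) else
    rep(0, ncol(counts))
  p_mito <- unname(ifelse(n_counts > 0, mito_counts / pmax(n_counts, 1), 0))

  max_counts <- thresholds$max_counts %||% as.numeric(quantile(n_counts, 0.995))
  fail <- tibble::tibble(
    low_features = n_features < thresholds$min_features,
    high_features = n_features > thresholds$max_features,
    low_counts = n_counts < thresholds$min_counts,
    high_counts = n_counts > max_counts,
    high_pmito = p_mito > thresholds$max_pmito
  )
  kept <- !Reduce(`|`, fail)
  if (!any(kept)) abort("empty after QC: thresholds removed every cell")

  report <- dplyr::bind_cols(
    tibble::tibble(barcode = colnames(counts), n_features = as.integer(n_features),
                   n_counts = n_counts, p_mito = p_mito, kept = kept),
    fail
  )
  tally <- tibble::tibble(
    rule = names(fail),
    removed = unname(vapply(fail, sum, integer(1)))
  )
  structure(list(counts = counts[, kept, drop = FALSE], report = report,
                 tally = tally, thresholds = thresholds,
                 max_counts_used = max_counts),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> kept ", sum(x$report$kept), " of ", nrow(x$report), " cells\n", sep = "")
  print(x$tally)
  invisible(x)
}
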