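# broom-style tidiers for the package's result objects.

#' @describeIn qc_filter `tidy()` returns the per-cell QC report.
#' @param x A `qc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) x$report

#' @describeIn qc_filter `glance()` returns a one-row summary with kept/removed
#'   counts and per-rule tallies.
#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) {
  tallies <- setNames(as.list(x$tally$removed), paste0("removed_", x$tally$rule))
  tibble::tibble(n_cells = nrow(x$report), n_kept = sum(x$report$kept),
                 n_removed = sum(!x$report$kept), !!!tallies,
                 max_counts_used = x$max_counts_used)
}

#' @describeIn identity_fraction_report `tidy()` stacks the three report tables
#'   into one long tibble with a `metric` column.
#' @param x A `fraction_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fraction_report <- function(x, ...) {
  dplyr::bind_rows(
    x$identity_percent |>
      dplyr::transmute(metric = "identity_percent",
                       key = as.character(.data$identity), value = .data$percent),
    x$dual_among_positive |>
      dplyr::transmute(metric = "dual_among_positive", key = .data$gene,
                       value = .data$percent_dual),
    x$marker_fraction_in_dual |>
      dplyr::transmute(metric = "marker_fraction_in_dual", key = .data$gene,
                       value = .data$percent_expressing)
  )
}

#' @describeIn run_pipeline `tidy()` returns the per-cell annotation table
#'   (QC stats, doublet scores, cluster, identity, module scores).
#' @param x A `limb_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.limb_result <- function(x, ...) x$cell_table

#' @describeIn run_pipeline `glance()` returns a one-row run summary.
#' @exportS3Method generics::glance
glance.limb_result <- function(x, ...) {
  ip <- x$fractions$identity_percent
  pct <- setNames(as.list(ip$percent), paste0("pct_", tolower(as.character(ip$identity))))
  tibble::tibble(
    n_cells_input = x$manifest$n_cells_input,
    n_cells_retained = x$manifest$n_cells_retained,
    n_doublets_removed = if (is.null(x$doublet_scores)) 0L else
      sum(x$doublet_scores$is_doublet_call),
    n_clusters = x$manifest$n_clusters,
    !!!pct,
    seed = x$manifest$seed,
    config_hash = x$manifest$config_hash
  )
}

#' @describeIn recovery_benchmark `tidy()` returns the per-run metric rows.
#' @param x A `recovery_benchmark`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.recovery_benchmark <- function(x, ...) x$runs

#' @describeIn recovery_benchmark `glance()` returns the per-grid-point summary.
#' @exportS3Method generics::glance
glance.recovery_benchmark <- function(x, ...) x$summary

#' @describeIn de_dual_vs_union `tidy()` returns the full differential table;
#'   use `x$biphasic` for the marker-panel summary.
#' @param x A `dual_de`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dual_de <- function(x, ...) x$table
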