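# ggplot2 displays for the main result types. Each returns a ggplot object.

#' Plot QC statistic distributions
#'
#' Histograms of nFeatures, nCounts and pMito with the applied thresholds.
#'
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_result <- function(object, ...) {
  long <- object$report |>
    tidyr::pivot_longer(c("n_features", "n_counts", "p_mito"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$kept)) +
    ggplot2::geom_histogram(bins = 60, position = "stack") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "cells", fill = "kept",
                  title = "Per-cell quality control") +
    ggplot2::theme_minimal()
}

#' Plot doublet score distributions
#'
#' @param object A `doublet_scores` tibble (after [call_doublets()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.doublet_scores <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$adjusted_score[!is.finite(df$adjusted_score)] <-
    max(df$adjusted_score[is.finite(df$adjusted_score)], 1) * 1.1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adjusted_score,
                                   fill = .data$is_doublet_call)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "adjusted doublet score", y = "cells",
                  fill = "called doublet") +
    ggplot2::theme_minimal()
}

#' Box plots of CT and M module scores by identity
#'
#' The canonical display for the intermediate-score property: dual cells
#' should sit between the CT and M groups on both scores.
#'
#' @param result A `limb_result` from [run_pipeline()], or a `score_table`
#'   together with `labels`.
#' @param labels Optional identity labels when `result` is a `score_table`.
#' @return A ggplot object.
#' @export
plot_scores_by_identity <- function(result, labels = NULL) {
  if (inherits(result, "limb_result")) {
    df <- dplyr::inner_join(tibble::as_tibble(result$scores), result$labels,
                            by = "barcode")
  } else {
    df <- dplyr::inner_join(tibble::as_tibble(result), labels, by = "barcode")
  }
  df <- df |>
    dplyr::filter(.data$identity %in% c("CT", "CT_M", "M")) |>
    tidyr::pivot_longer(c("ct_score", "m_score"),
                        names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$identity, y = .data$value,
                                   fill = .data$identity)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~score) +
    ggplot2::scale_fill_manual(values = c(CT = "#d53e4f", CT_M = "#66c164",
                                          M = "#3288bd")) +
    ggplot2::labs(x = NULL, y = "module score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' PC scatter coloured by cluster or identity
#'
#' @param result A `limb_result`.
#' @param colour `"cluster"` or `"identity"`.
#' @param dims Two PC indices (default 1:2).
#' @return A ggplot object.
#' @export
plot_embedding <- function(result, colour = c("cluster", "identity"), dims = c(1, 2)) {
  colour <- match.arg(colour)
  sc <- result$embedding$scores[, dims, drop = FALSE]
  df <- tibble::tibble(barcode = rownames(sc), x = sc[, 1], y = sc[, 2]) |>
    dplyr::inner_join(result$labels, by = "barcode") |>
    dplyr::mutate(cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table` from [find_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglog10 <- -log10(pmax(df$p_adj, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_fc, y = .data$neglog10,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "ln fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
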