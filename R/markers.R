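#' Connective-tissue and muscle marker panel
#'
#' The dual-identity rule and the CT/M module scores are driven by two small
#' disjoint marker sets: connective-tissue (CT) fibroblast markers and
#' myogenic (M) markers. The defaults are the canonical chicken limb panels:
#' CT = PRRX1, TWIST2, PDGFRA, OSR1, SCX and M = PAX7, MYF5, MYOD1, MYOG.
#'
#' `MYOD` is accepted as an alias of `MYOD1` when feature tables are read
#' (see [read_dataset()]).
#'
#' @param ct_genes Character vector of CT marker gene symbols.
#' @param m_genes Character vector of muscle marker gene symbols.
#' @return A `marker_panel` object (list with `ct_genes` and `m_genes`).
#' @examples
#' marker_panel()
#' @export
marker_panel <- function(ct_genes = c("PRRX1", "TWIST2", "PDGFRA", "OSR1", "SCX"),
                         m_genes = c("PAX7", "MYF5", "MYOD1", "MYOG")) {
  ct_genes <- unique(as.character(ct_genes))
  m_genes <- unique(as.character(m_genes))
  if (length(ct_genes) == 0 || length(m_genes) == 0) {
    abort("both marker sets must be non-empty")
  }
  if (length(intersect(ct_genes, m_genes)) > 0) {
    abort(paste0(
      "CT and M marker sets must be disjoint; shared: ",
      paste(intersect(ct_genes, m_genes), collapse = ", ")
    ))
  }
  structure(list(ct_genes = ct_genes, m_genes = m_genes), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  cat("  CT:", paste(x$ct_genes, collapse = ", "), "\n")
  cat("  M: ", paste(x$m_genes, collapse = ", "), "\n")
  invisible(x)
}
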