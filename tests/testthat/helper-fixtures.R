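# Shared fixtures, generated in code at test time.

# Small but non-trivial mixture used by several module tests.
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(
    n_cells = c(CT = 250, M = 250, OTHER_1 = 100),
    dual_fraction = 0.06, doublet_rate = 0.05, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_dataset <- function(seed = 42, ...) {
  simulate_counts(small_sim_config(seed = seed, ...))
}

# Wrap a plain genes x cells matrix as a normalized_matrix for functions that
# operate on log-normalized values directly.
as_norm <- function(m, scale_factor = 1) {
  structure(list(values = Matrix::Matrix(m, sparse = TRUE), scale_factor = scale_factor),
            class = "normalized_matrix")
}

# A tiny matrix over the default marker panel plus filler genes.
panel_matrix <- function(cells) {
  genes <- c(marker_panel()$ct_genes, marker_panel()$m_genes, "ID1", "HK-1", "HK-2")
  cell_names <- if (is.null(names(cells))) paste0("c", seq_along(cells)) else names(cells)
  m <- matrix(0, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cell_names))
  for (i in seq_along(cells)) {
    v <- cells[[i]]
    m[names(v), i] <- v
  }
  m
}
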