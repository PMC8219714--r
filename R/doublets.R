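#' Simulate synthetic doublet profiles
#'
#' Forms `n_sim` artificial doublet expression profiles, each the raw count sum
#' of two distinct observed cells sampled uniformly. Their barcodes carry the
#' reserved `SIMDBL:` prefix and never appear in downstream outputs.
#'
#' @param counts Sparse genes x cells count matrix (or `limb_dataset`/`qc_result`).
#' @param n_sim Number of simulated doublets (default 2x the observed cells).
#' @param seed Integer seed for parent sampling.
#' @return Sparse genes x n_sim count matrix.
#' @export
simulate_synthetic_doublets <- function(counts, n_sim = NULL, seed = 1L) {
  if (inherits(counts, "limb_dataset") || inherits(counts, "qc_result")) counts <- counts$counts
  n <- ncol(counts)
  if (n < 2) abort("need at least 2 cells to simulate doublets")
  n_sim <- n_sim %||% (2L * n)
  if (n_sim < 1) abort("n_sim must be >= 1")
  set.seed(seed)
  p1 <- sample.int(n, n_sim, replace = TRUE)
  shift <- sample.int(n - 1L, n_sim, replace = TRUE)
  p2 <- ((p1 - 1L + shift) %% n) + 1L  # uniform over cells != p1
  sim <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(sim) <- sprintf("SIMDBL:%06d", seq_len(n_sim))
  sim
}

#' Score cells for doublet likelihood against simulated doublets
#'
#' The simulated-doublet nearest-neighbour method: observed and simulated
#' profiles are jointly log-normalized (so library-size depth is removed and
#' discrimination must come from mixed expression), variable genes and the PCA
#' basis are fitted on the observed cells only, simulated profiles are
#' projected into that space, and each observed cell receives
#' \itemize{
#'   \item a raw score: the fraction of its `k_neighbors` nearest neighbours
#'     (among observed + simulated) that are simulated, and
#'   \item an adjusted score: the odds `raw / (1 - raw)` corrected for the
#'     simulated:observed imbalance by `n_obs / n_sim` (a cell whose every
#'     neighbour is simulated scores `Inf`).
#' }
#'
#' @param observed Sparse genes x cells count matrix (or `limb_dataset`/`qc_result`).
#' @param simulated Matrix from [simulate_synthetic_doublets()].
#' @param k_neighbors Neighbourhood size; default `round(0.5 * sqrt(n_obs + n_sim))`.
#' @param n_pcs Number of PCs (capped at the variable-gene count).
#' @param n_hvg Number of variable genes fitted on the observed cells.
#' @param seed Integer seed (kept in the output for provenance).
#' @return A `doublet_scores` tibble (`barcode`, `raw_score`, `adjusted_score`,
#'   `is_doublet_call`) with scoring parameters as attributes.
#' @seealso [call_doublets()]
#' @export
score_doublets <- function(observed, simulated, k_neighbors = NULL, n_pcs = 30,
                           n_hvg = 1000, seed = 1L) {
  if (inherits(observed, "limb_dataset") || inherits(observed, "qc_result")) observed <- observed$counts
  if (ncol(simulated) < 1) abort("simulated profile set is empty")
  n_obs <- ncol(observed)
  n_sim <- ncol(simulated)
  k_neighbors <- k_neighbors %||% max(3L, round(0.5 * sqrt(n_obs + n_sim)))
  if (k_neighbors >= n_obs + n_sim) abort("k_neighbors must be below the combined cell count")

  joint <- log_normalize(cbind(observed, simulated))
  norm_obs <- structure(list(values = joint$values[, seq_len(n_obs), drop = FALSE],
                             scale_factor = joint$scale_factor),
                        class = "normalized_matrix")
  norm_sim <- structure(list(values = joint$values[, n_obs + seq_len(n_sim), drop = FALSE],
                             scale_factor = joint$scale_factor),
                        class = "normalized_matrix")
  hvg <- select_hvg(norm_obs, n_hvg = min(n_hvg, nrow(observed)))
  n_pcs <- min(n_pcs, length(hvg))
  emb <- embed_pca(norm_obs, hvg, n_pcs = n_pcs)
  sim_scores <- .project_embedding(emb, norm_sim)
  all_scores <- rbind(emb$scores, sim_scores)

  nn <- .knn_indices(emb$scores, all_scores, k = k_neighbors, self = seq_len(n_obs))
  raw <- rowMeans(matrix(nn > n_obs, nrow = n_obs))
  adjusted <- ifelse(raw < 1, raw / (1 - raw) * (n_obs / n_sim), Inf)

  out <- tibble::tibble(barcode = colnames(observed), raw_score = raw,
                        adjusted_score = adjusted, is_doublet_call = NA)
  attr(out, "n_simulated") <- n_sim
  attr(out, "k_neighbors") <- k_neighbors
  attr(out, "n_pcs") <- n_pcs
  attr(out, "seed") <- seed
  class(out) <- c("doublet_scores", class(out))
  out
}

#' Call doublets from adjusted scores
#'
#' `"fixed_threshold"` flags cells with adjusted score strictly above `param`;
#' `"fixed_quantile"` flags the top `param` fraction of cells by adjusted score
#' (exactly `round(param * n)` calls, ties broken by barcode order).
#'
#' @param scores A `doublet_scores` tibble from [score_doublets()].
#' @param strategy `"fixed_quantile"` or `"fixed_threshold"`.
#' @param param Quantile in (0, 1) or score threshold.
#' @return The `doublet_scores` tibble with `is_doublet_call` filled in and the
#'   strategy recorded as attributes.
#' @export
call_doublets <- function(scores, strategy = c("fixed_quantile", "fixed_threshold"),
                          param = 0.05) {
  strategy <- match.arg(strategy)
  n <- nrow(scores)
  if (strategy == "fixed_quantile") {
    if (!is.numeric(param) || param <= 0 || param >= 1) {
      abort("quantile param must lie in (0, 1)")
    }
    n_call <- round(param * n)
    ord <- order(-scores$adjusted_score, seq_len(n))
    call <- logical(n)
    call[ord[seq_len(n_call)]] <- TRUE
  } else {
    call <- scores$adjusted_score > param
  }
  scores$is_doublet_call <- call
  attr(scores, "strategy") <- strategy
  attr(scores, "threshold") <- param
  scores
}
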