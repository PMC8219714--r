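#' PCA embedding of scaled variable-gene expression
#'
#' Centres and unit-scales each variable gene across cells (scaled values are
#' capped above at `scale_cap` so rare extreme cells cannot dominate a
#' component), optionally residualizes each gene on per-cell covariates by
#' least squares before scaling (e.g. cell-cycle scores), and returns the top
#' principal components.
#'
#' @param norm A `normalized_matrix` from [log_normalize()].
#' @param hvg Character vector of genes to embed (subset of rownames).
#' @param n_pcs Number of components (>= 2, <= length(hvg)).
#' @param covariates Optional per-cell numeric matrix/data frame to regress out.
#' @param scale_cap Upper cap applied to scaled values (default 10).
#' @return A `limb_embedding`: list with `scores` (cells x n_pcs, rownames =
#'   barcodes), `loadings` (genes x n_pcs), `variance_explained` (non-increasing),
#'   `hvg_used`, and the centring/scaling parameters used (for projection).
#' @export
embed_pca <- function(norm, hvg, n_pcs = 30, covariates = NULL, scale_cap = 10) {
  if (!inherits(norm, "normalized_matrix")) abort("norm must be a normalized_matrix")
  if (n_pcs < 2) abort("n_pcs must be >= 2")
  if (n_pcs > length(hvg)) abort("n_pcs exceeds the number of variable genes")
  .assert_genes_present(hvg, rownames(norm$values))
  X <- as.matrix(Matrix::t(norm$values[hvg, , drop = FALSE]))

  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != nrow(X)) abort("covariates must have one row per cell")
    X <- stats::lm.fit(cbind(1, C), X)$residuals
    dimnames(X) <- list(colnames(norm$values), hvg)
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  # genes with (numerically) no variance are left centred at zero rather
  # than amplified by a vanishing divisor
  tol <- 1e-10 * max(sds, 1)
  scl <- ifelse(sds > tol, sds, Inf)
  X <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  X[X > scale_cap] <- scale_cap

  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    variance_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
    hvg_used = hvg,
    center = ctr, scale = scl, scale_cap = scale_cap
  ), class = "limb_embedding")
}

# Project new cells into an existing embedding with its stored
# centring/scaling parameters (used for simulated doublets).
.project_embedding <- function(embedding, norm_new) {
  X <- as.matrix(Matrix::t(norm_new$values[embedding$hvg_used, , drop = FALSE]))
  X <- sweep(sweep(X, 2, embedding$center), 2, embedding$scale, `/`)
  X[X > embedding$scale_cap] <- embedding$scale_cap
  X %*% embedding$loadings
}

#' @export
print.limb_embedding <- function(x, ...) {
  cat("<limb_embedding> ", nrow(x$scores), " cells x ", ncol(x$scores), " PCs (",
      length(x$hvg_used), " variable genes)\n", sep = "")
  invisible(x)
}

# k nearest neighbours (Euclidean) of each row of `query` among rows of `ref`,
# computed in chunks; ties broken by reference row order. `self` gives, for
# each query row, the index in `ref` to exclude (NA = none).
.knn_indices <- function(query, ref, k, self = NULL, chunk = 1024L) {
  if (k >= nrow(ref)) abort("k_neighbors must be smaller than the number of cells")
  ref_sq <- rowSums(ref^2)
  out <- matrix(0L, nrow = nrow(query), ncol = k)
  for (start in seq(1, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref_sq, `+`) - 2 * tcrossprod(q, ref)
    if (!is.null(self)) {
      sel <- cbind(seq_along(idx), self[idx])
      sel <- sel[!is.na(sel[, 2]), , drop = FALSE]
      if (nrow(sel) > 0) d2[sel] <- Inf
    }
    for (i in seq_along(idx)) {
      v <- d2[i, ]
      th <- sort.int(v, partial = k)[k]
      cand <- which(v <= th)
      cand <- cand[order(v[cand], cand)]  # ties broken by reference order
      out[idx[i], ] <- cand[seq_len(k)]
    }
  }
  out
}

#' Graph-based clustering of cells in PC space
#'
#' Builds an unweighted k-nearest-neighbour graph on the PC scores (Euclidean
#' distance, ties broken by barcode order) and partitions it by
#' modularity-based community detection (Louvain) at the given resolution.
#' Cells are processed in barcode order internally, so the partition is
#' invariant to the input ordering of cells, and a fixed seed gives an
#' identical assignment. Cluster ids are contiguous from 0, ordered by
#' decreasing cluster size.
#'
#' @param embedding A `limb_embedding` from [embed_pca()].
#' @param k_neighbors Number of neighbours for the graph (default 20).
#' @param resolution Modularity resolution (default 1).
#' @param seed Integer seed.
#' @return A `cluster_assignment` tibble (`barcode`, `cluster`) with the
#'   parameters stored as attributes.
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 1.0, seed = 1L) {
  scores <- embedding$scores
  n <- nrow(scores)
  if (k_neighbors >= n) abort("fewer cells than k_neighbors + 1")
  ord <- order(rownames(scores))
  S <- scores[ord, , drop = FALSE]
  nn <- .knn_indices(S, S, k = k_neighbors, self = seq_len(n))
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  cluster_sorted <- unname(relabel[as.character(memb)])
  cluster <- integer(n)
  cluster[ord] <- cluster_sorted

  out <- tibble::tibble(barcode = rownames(scores), cluster = as.integer(cluster))
  attr(out, "resolution") <- resolution
  attr(out, "k_neighbors") <- k_neighbors
  attr(out, "seed") <- seed
  class(out) <- c("cluster_assignment", class(out))
  out
}
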