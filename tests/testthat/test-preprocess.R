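test_that("qc_filter applies each threshold and the degenerate-cell convention", {
  m <- Matrix::Matrix(matrix(c(
    0, 0, 0,        # zero-count cell: pMito defined as 0, removed by min_counts
    90, 10, 0,      # 10% mito of 100 -> removed at max_pmito 0.05
    300, 5, 200     # healthy cell
  ), nrow = 3, dimnames = list(c("HK-1", "MT-1", "HK-2"), c("c0", "c1", "c2"))),
  sparse = TRUE)
  qc <- qc_filter(m, qc_thresholds(min_features = 1, min_counts = 50,
                                   max_counts = 1e6, max_pmito = 0.05))
  expect_equal(qc$report$p_mito, c(0, 0.10, 5 / 505))
  expect_equal(qc$report$kept, c(FALSE, FALSE, TRUE))
  expect_equal(qc$tally$removed[qc$tally$rule == "high_pmito"], 1L)
  expect_equal(colnames(qc$counts), "c2")
  expect_error(qc_filter(m, qc_thresholds(min_counts = 1e7)), "empty after QC")
})

test_that("qc removal tally for pMito recovers the planted high-mito cells", {
  ds <- small_dataset(seed = 8, doublet_rate = 0, mito_high_fraction = 0.1,
                      n_cells = c(CT = 400, M = 400))
  qc <- qc_filter(ds)
  expect_equal(qc$tally$removed[qc$tally$rule == "high_pmito"],
               sum(ds$truth$mito_high))
  flagged <- ds$truth$barcode[ds$truth$mito_high]
  expect_true(all(qc$report$high_pmito[qc$report$barcode %in% flagged]))
})

test_that("qc_filter with fixed thresholds is idempotent", {
  ds <- small_dataset(seed = 8)
  th <- qc_thresholds(max_counts = as.numeric(quantile(Matrix::colSums(ds$counts), 0.995)))
  once <- qc_filter(ds, th)
  twice <- qc_filter(once$counts, th)
  expect_identical(colnames(twice$counts), colnames(once$counts))
  expect_true(all(twice$report$kept))
})

test_that("log normalization follows the median-scale formula and is monotone", {
  m <- Matrix::Matrix(matrix(c(2, 0, 8, 10, 0, 10, 15, 0, 15), nrow = 3,
                             dimnames = list(c("a", "b", "c"),
                                             c("c1", "c2", "c3"))), sparse = TRUE)
  n <- log_normalize(m)  # totals 10, 20, 30 -> s = 20
  expect_equal(n$scale_factor, 20)
  expect_equal(n$values["a", "c1"], log(5))       # ln(1 + 2/10*20)
  expect_equal(as.numeric(n$values["b", ]), c(0, 0, 0))  # all-zero gene stays zero

  # strict monotonicity within a cell
  ds <- small_dataset(seed = 4, n_cells = c(CT = 50, M = 50))
  nv <- log_normalize(qc_filter(ds)$counts)
  cell <- as.numeric(qc_filter(ds)$counts[, 1])
  val <- as.numeric(nv$values[, 1])
  ord <- order(cell)
  expect_true(all(diff(val[ord])[diff(cell[ord]) > 0] > 0))

  # doubling a cell's counts is absorbed entirely by the depth scaling
  # when the scale factor is held fixed
  m2 <- m
  m2[, "c1"] <- m2[, "c1"] * 2
  n2 <- log_normalize(m2, scale_factor = 20)
  nf <- log_normalize(m, scale_factor = 20)
  expect_equal(n2$values[, "c1"], nf$values[, "c1"])

  m_zero <- m
  m_zero[, "c1"] <- 0
  expect_error(log_normalize(m_zero), "qc_filter")
})

test_that("variable-gene selection ranks by binned standardized dispersion", {
  vals <- rbind(g_flat = c(1, 1, 1), g_mid = c(0, sqrt(0.2), 0),
                g_hi = c(0, 1, 0.5))
  colnames(vals) <- paste0("c", 1:3)
  norm <- as_norm(vals)
  expect_equal(select_hvg(norm, n_hvg = 1, n_bins = 1), "g_hi")
  expect_false("g_flat" %in% select_hvg(norm, n_hvg = 2, n_bins = 1))
  expect_error(select_hvg(norm, n_hvg = 0), "n_hvg")
  expect_error(select_hvg(norm, n_hvg = 10), "exceeds")
})

test_that("programme genes outrank housekeeping genes in dispersion", {
  ds <- small_dataset(seed = 6, dual_fraction = 0, doublet_rate = 0)
  norm <- log_normalize(qc_filter(ds)$counts)
  ranking <- select_hvg(norm, n_hvg = nrow(norm$values) - 1)
  rk <- match(rownames(norm$values), ranking)
  prog <- grepl("^PRG-", rownames(norm$values))
  hk <- grepl("^HK-", rownames(norm$values))
  expect_lt(median(rk[prog], na.rm = TRUE), median(rk[hk], na.rm = TRUE))
})

test_that("PCA embedding honours duplicates, rank-1 data and covariates", {
  set.seed(1)
  vals <- matrix(rnorm(20 * 30), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  vals[, 2] <- vals[, 1]  # duplicated cell
  emb <- embed_pca(as_norm(vals), hvg = paste0("g", 1:20), n_pcs = 5)
  expect_equal(emb$scores[1, ], emb$scores[2, ])
  expect_true(all(diff(emb$variance_explained) <= 1e-12))

  # rank-1 case: all cells on one line through the centroid
  line <- outer(rnorm(10), seq(-1, 1, length.out = 12))
  dimnames(line) <- list(paste0("g", 1:10), paste0("c", 1:12))
  emb1 <- embed_pca(as_norm(line), hvg = paste0("g", 1:10), n_pcs = 3,
                    scale_cap = Inf)
  expect_equal(emb1$variance_explained[1], 1, tolerance = 1e-10)

  # regressing a gene on itself removes its contribution
  cov <- vals["g1", ]
  emb2 <- embed_pca(as_norm(vals), hvg = paste0("g", 1:20), n_pcs = 5,
                    covariates = cov)
  expect_lt(max(abs(emb2$loadings["g1", ])), 1e-8)

  expect_error(embed_pca(as_norm(vals), hvg = paste0("g", 1:3), n_pcs = 5),
               "exceeds")
  expect_error(embed_pca(as_norm(vals), hvg = paste0("g", 1:3), n_pcs = 1),
               ">= 2")
})

test_that("clustering separates blobs, merges homogeneous data, ignores order", {
  set.seed(7)
  blob <- function(center, n, prefix) {
    m <- matrix(rnorm(n * 5, sd = 0.3), ncol = 5) +
      matrix(center, nrow = n, ncol = 5, byrow = TRUE)
    rownames(m) <- sprintf("%s%03d", prefix, seq_len(n))
    m
  }
  scores <- rbind(blob(c(10, 0, 0, 0, 0), 60, "a"), blob(c(-10, 0, 0, 0, 0), 60, "b"))
  emb <- structure(list(scores = scores), class = "limb_embedding")
  cl <- cluster_cells(emb, k_neighbors = 10, resolution = 1, seed = 1)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  truth <- rep(c("A", "B"), each = 60)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)

  one <- structure(list(scores = blob(rep(0, 5), 80, "x")), class = "limb_embedding")
  cl1 <- cluster_cells(one, k_neighbors = 15, resolution = 0.1, seed = 1)
  expect_equal(dplyr::n_distinct(cl1$cluster), 1)

  perm <- sample(nrow(scores))
  embp <- structure(list(scores = scores[perm, ]), class = "limb_embedding")
  clp <- cluster_cells(embp, k_neighbors = 10, resolution = 1, seed = 1)
  joined <- dplyr::inner_join(cl, clp, by = "barcode")
  expect_equal(mclust::adjustedRandIndex(joined$cluster.x, joined$cluster.y), 1)

  expect_error(cluster_cells(one, k_neighbors = 100), "fewer cells")
})
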