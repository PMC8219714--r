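make_two_group_norm <- function(n_per = 40, n_genes = 30, up_gene = "g01",
                                seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  m <- matrix(rpois(n_genes * 2 * n_per, 3), nrow = n_genes,
              dimnames = list(genes, sprintf("c%03d", seq_len(2 * n_per))))
  m[up_gene, seq_len(n_per)] <- m[up_gene, seq_len(n_per)] + 15
  norm <- log_normalize(Matrix::Matrix(m, sparse = TRUE))
  # a gene constant on the normalized scale (depth scaling would otherwise
  # re-introduce variation from the cells' differing totals)
  norm$values["g02", ] <- 1.5
  groups <- tibble::tibble(barcode = colnames(m),
                           group = rep(c("A", "B"), each = n_per))
  list(norm = norm, groups = groups)
}

test_that("find_markers recovers a planted group marker", {
  fx <- make_two_group_norm()
  de <- find_markers(fx$norm, fx$groups, min_pct = 0.1, logfc_min = 0.1)
  hit <- de[de$gene == "g01" & de$group == "A", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$significant)
  expect_gt(hit$log_fc, 0)
  expect_equal(hit$direction, "up")
  # the same gene is down-flagged for the other group
  expect_equal(de$direction[de$gene == "g01" & de$group == "B"], "down")
  # constant gene never appears as significant
  expect_false(any(de$significant[de$gene == "g02"]))
  # table sorted by group then adjusted p
  expect_true(!is.unsorted(de$group))
  expect_true(all(tapply(de$p_adj, de$group, function(x) !is.unsorted(x))))
})

test_that("find_markers warns on tiny groups and top_markers caps output", {
  fx <- make_two_group_norm()
  g <- fx$groups
  g$group[1:2] <- "TINY"
  expect_warning(find_markers(fx$norm, g), "fewer than 3")
  de <- find_markers(fx$norm, fx$groups, logfc_min = 0)
  top <- top_markers(de, n = 3)
  expect_true(all(table(top$group) <= 3))
  expect_true(all(top$direction == "up"))
})

test_that("permuted labels control the false-positive rate", {
  set.seed(6)
  m <- matrix(rpois(50 * 200, 2), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200)))
  m[, 1] <- m[, 1] + 1  # guard against all-zero cells
  norm <- log_normalize(Matrix::Matrix(m, sparse = TRUE))
  n_sig <- vapply(1:100, function(i) {
    set.seed(i)
    grp <- tibble::tibble(barcode = colnames(m),
                          group = sample(rep(c("A", "B"), each = 100)))
    de <- find_markers(norm, grp, min_pct = 0, logfc_min = 0)
    sum(de$significant)
  }, numeric(1))
  # under the global null the false-discovery event rate equals P(any
  # rejection), which BH holds at alpha; allow binomial Monte-Carlo slack
  p_any <- mean(n_sig > 0)
  expect_lte(p_any, 0.05 + 3 * sqrt(0.05 * 0.95 / length(n_sig)))
})

test_that("dual-vs-union differential expression summarises the planted trajectory", {
  ds <- simulate_counts(sim_config(n_cells = c(CT = 350, M = 350),
                                   dual_fraction = 0.3, doublet_rate = 0,
                                   biphasic_mode = "late", seed = 17))
  norm <- log_normalize(qc_filter(ds)$counts)
  pop <- ds$truth$population[match(colnames(norm$values), ds$truth$barcode)]
  labels <- tibble::tibble(
    barcode = colnames(norm$values),
    identity = dplyr::case_when(pop == "CT" ~ "CT", pop == "M" ~ "M",
                                TRUE ~ "CT_M")
  )
  dd <- de_dual_vs_union(norm, labels)
  expect_equal(dd$status, "ok")
  bi <- dd$biphasic
  ct <- bi[bi$side == "ct", ]
  m_ <- bi[bi$side == "m", ]
  # late stage: every CT marker down versus CT cells,
  # every muscle marker up versus the combined pool
  expect_true(all(ct$log_fc_vs_own < 0 & ct$p_adj_vs_own < 0.05))
  expect_true(all(m_$log_fc_vs_union > 0 & m_$significant_vs_union))
})

test_that("dual-vs-union with no dual cells reports a status, not an error", {
  fx <- make_two_group_norm()
  labels <- tibble::tibble(barcode = fx$groups$barcode,
                           identity = rep(c("CT", "M"), each = 40))
  dd <- de_dual_vs_union(fx$norm, labels,
                         panel = marker_panel(ct_genes = "g01", m_genes = "g03"))
  expect_equal(dd$status, "no dual cells")
  expect_equal(nrow(dd$table), 0)
})

test_that("expressing-fraction comparison matches the Fisher oracle", {
  m <- matrix(0, nrow = 2, ncol = 20,
              dimnames = list(c("ID1", "HK-1"), sprintf("c%02d", 1:20)))
  m["ID1", c(1:8, 11:12)] <- 1  # 8/10 in group A, 2/10 in group B
  labels <- tibble::tibble(barcode = colnames(m),
                           identity = rep(c("A", "B"), each = 10))
  out <- fraction_expressing_compare(as_norm(m), "ID1", labels, "A", "B")
  expect_equal(out$frac_a[1], 0.8)
  expect_equal(out$frac_b[1], 0.2)
  expect_equal(out$p[1], 0.023014, tolerance = 1e-4)
  # identical groups give p = 1
  same <- fraction_expressing_compare(as_norm(m), "ID1", labels, "A", "A")
  expect_equal(same$p, rep(1, 2))
})

test_that("planted ID-gene signal elevates the dual expressing fraction", {
  ds <- simulate_counts(sim_config(n_cells = c(CT = 350, M = 350),
                                   dual_fraction = 0.3, doublet_rate = 0, seed = 23))
  norm <- log_normalize(qc_filter(ds)$counts)
  pop <- ds$truth$population[match(colnames(norm$values), ds$truth$barcode)]
  labels <- tibble::tibble(
    barcode = colnames(norm$values),
    identity = dplyr::case_when(pop == "CT" ~ "CT", pop == "M" ~ "M",
                                TRUE ~ "CT_M")
  )
  for (ref in c("CT", "M")) {
    out <- fraction_expressing_compare(norm, c("ID1", "ID2", "ID3"), labels,
                                       "CT_M", ref)
    expect_true(all(out$frac_a > out$frac_b))
    expect_true(all(out$p[out$gene != "pooled"] < 0.05))
  }
})
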