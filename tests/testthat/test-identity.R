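test_that("the dual call implements the co-expression rule exactly", {
  m <- panel_matrix(list(
    both_one = c(PRRX1 = 1.2, PAX7 = 0.4),
    ct_only = c(PRRX1 = 2, TWIST2 = 1, PDGFRA = 1, OSR1 = 3, SCX = 0.5),
    scx_myog = c(SCX = 0.01, MYOG = 0.01),
    none = c(`HK-1` = 0),
    m_only = c(PAX7 = 1, MYF5 = 2, MYOD1 = 1, MYOG = 1)
  ))
  dual <- call_dual(as_norm(m))
  expect_equal(dual$is_dual, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("turning any zero marker positive never revokes a dual call", {
  set.seed(2)
  pn <- marker_panel()
  m <- panel_matrix(list(a = c(PRRX1 = 1, PAX7 = 1), b = c(SCX = 2, MYOG = 0.1),
                         c = c(OSR1 = 1)))
  before <- call_dual(as_norm(m))$is_dual
  for (g in c(pn$ct_genes, pn$m_genes)) {
    for (cell in colnames(m)) {
      if (m[g, cell] == 0) {
        m2 <- m
        m2[g, cell] <- runif(1, 0.1, 2)
        after <- call_dual(as_norm(m2))$is_dual
        expect_true(all(after[before]))
      }
    }
  }
})

test_that("missing panel genes are reported by name", {
  m <- matrix(1, nrow = 2, ncol = 1, dimnames = list(c("PRRX1", "PAX7"), "c1"))
  expect_error(call_dual(as_norm(m)), "TWIST2")
})

test_that("module score matches the one-bin hand computation", {
  m <- matrix(c(2, 0, 1, 1), nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"), "cell1"))
  s <- module_score(m, "g1", n_bins = 1, n_ctrl = 3, seed = 1)
  expect_equal(unname(s), 4 / 3, tolerance = 1e-12)
})

test_that("module score is exactly invariant under a global additive shift", {
  set.seed(3)
  m <- matrix(rexp(50 * 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  set <- c("g05", "g17", "g33")
  s0 <- module_score(m, set, n_bins = 5, n_ctrl = 4, seed = 9)
  s1 <- module_score(m + 0.73, set, n_bins = 5, n_ctrl = 4, seed = 9)
  expect_equal(s0, s1, tolerance = 1e-12)
})

test_that("a random gene set from one bin scores near zero on average", {
  set.seed(4)
  m <- matrix(rpois(60 * 200, 5) / 2, nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("c%03d", 1:200)))
  mu <- rowMeans(m)
  bin <- dplyr::ntile(rank(mu, ties.method = "first"), 5)
  pool <- rownames(m)[bin == 3]
  means <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    gs <- sample(pool, 3)
    mean(module_score(m, gs, n_bins = 5, n_ctrl = 10, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)))
})

test_that("module score is deterministic in its seed and validates inputs", {
  m <- matrix(runif(20 * 5), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), paste0("c", 1:5)))
  expect_identical(module_score(m, c("g01", "g02"), n_bins = 4, seed = 7),
                   module_score(m, c("g01", "g02"), n_bins = 4, seed = 7))
  expect_error(module_score(m, character(0)), "non-empty")
  expect_error(module_score(m, rownames(m)), "strict subset")
  two <- m[1:2, , drop = FALSE]
  expect_error(module_score(two, "g01", n_bins = 2, n_ctrl = 1), "control")
})

test_that("cluster annotation classifies by score margin with OTHER fallback", {
  ds <- simulate_counts(sim_config(n_cells = c(CT = 150, M = 150, OTHER_1 = 150),
                                   dual_fraction = 0, doublet_rate = 0, seed = 31))
  norm <- log_normalize(qc_filter(ds)$counts)
  pop <- ds$truth$population[match(colnames(norm$values), ds$truth$barcode)]
  clusters <- tibble::tibble(barcode = colnames(norm$values),
                             cluster = as.integer(factor(pop)) - 1L)
  ann <- annotate_clusters(norm, clusters, seed = 2)
  lookup <- ann$class[match(sort(unique(clusters$cluster)), ann$cluster)]
  pop_of_cluster <- tapply(pop, clusters$cluster, function(x) x[1])
  expect_equal(unname(lookup[pop_of_cluster == "CT"]), "CT")
  expect_equal(unname(lookup[pop_of_cluster == "M"]), "M")
  expect_equal(unname(lookup[pop_of_cluster == "OTHER_1"]), "OTHER")

  all_other <- annotate_clusters(norm, clusters, margin = 1e6, seed = 2)
  expect_true(all(all_other$class == "OTHER"))
})

test_that("identity assignment partitions cells with dual override", {
  clusters <- tibble::tibble(barcode = paste0("c", 1:6),
                             cluster = c(0L, 0L, 1L, 1L, 2L, 2L))
  classes <- tibble::tibble(cluster = 0:2, class = c("CT", "M", "OTHER"))
  dual <- tibble::tibble(barcode = paste0("c", 1:6),
                         is_dual = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  lab <- assign_identity(clusters, classes, dual)
  expect_equal(as.character(lab$identity),
               c("CT", "CT_M", "CT_M", "M", "CT_M", "OTHER"))
  expect_equal(sum(table(lab$identity)), 6)

  expect_error(assign_identity(clusters, classes[1:2, ], dual), "classified")
  expect_error(assign_identity(clusters, classes, dual[1:3, ]), "dual call")
})

test_that("fraction report arithmetic matches its definitions", {
  n <- 1000
  genes <- c(marker_panel()$ct_genes, marker_panel()$m_genes, "ID1")
  m <- matrix(0, nrow = length(genes), ncol = n,
              dimnames = list(genes, sprintf("c%04d", 1:n)))
  # 100 MYOG+ cells, of which 11 are labelled dual
  m["MYOG", 1:100] <- 1
  labels <- tibble::tibble(
    barcode = colnames(m),
    identity = factor(c(rep("CT_M", 11), rep("M", 89), rep("CT_M", 29),
                        rep("CT", 500), rep("OTHER", 371)),
                      levels = c("CT", "CT_M", "M", "OTHER"))
  )
  rep <- identity_fraction_report(labels, as_norm(m), probe_genes = c("MYOG", "ID1"))
  ip <- rep$identity_percent
  expect_equal(ip$percent[ip$identity == "CT_M"], 4.0)  # 40 of 1000
  expect_equal(sum(ip$percent), 100)
  dap <- rep$dual_among_positive
  expect_equal(dap$percent_dual[dap$gene == "MYOG"], 11)
  expect_true(is.na(dap$percent_dual[dap$gene == "ID1"]))
  mf <- rep$marker_fraction_in_dual
  expect_equal(mf$percent_expressing[mf$gene == "MYOG"], 100 * 11 / 40)
  expect_error(identity_fraction_report(labels, as_norm(m), probe_genes = "NOPE"),
               "NOPE")
})
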