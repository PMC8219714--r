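test_that("exact Wilcoxon matches the classical distribution for all small tie-free inputs", {
  # every rank configuration with n <= 10; values WLOG the ranks themselves
  for (n in 2:10) {
    for (nx in 1:(n - 1)) {
      for (idx in utils::combn(n, nx, simplify = FALSE)) {
        x <- idx
        y <- setdiff(1:n, idx)
        ours <- wilcoxon_rank_sum(x, y)
        ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
        expect_equal(ours$p, ref$p.value, tolerance = 1e-12,
                     info = paste("n =", n, "x =", paste(x, collapse = ",")))
        expect_equal(ours$statistic, unname(ref$statistic))
      }
    }
  }
})

test_that("one-sided exact Wilcoxon tails match the classical implementation", {
  set.seed(1)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    pool <- sample(500, nx + ny)  # tie-free across both samples
    x <- pool[1:nx]; y <- pool[(nx + 1):(nx + ny)]
    for (alt in c("less", "greater")) {
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                                 alternative = sub("_", ".", alt)))
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon handles degenerate and tied inputs", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 9))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # tie-corrected normal approximation against the classical implementation
  set.seed(2)
  for (i in 1:20) {
    x <- sample(0:4, 30, replace = TRUE)
    y <- sample(0:5, 25, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(wilcoxon_rank_sum(x, y)$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Wilcoxon type-I error is calibrated at the nominal level", {
  set.seed(11)
  reject <- vapply(1:1000, function(i) {
    x <- rnorm(50); y <- rnorm(50)
    wilcoxon_rank_sum(x, y)$p < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(mean(reject), ci[1])
  expect_lte(mean(reject), ci[2])
})

test_that("Fisher exact matches hypergeometric enumeration over a margins grid", {
  # exhaustive over all 2x2 tables with N <= 40 against a dhyper oracle
  for (N in 2:40) {
    worst <- 0
    for (m in 1:(N - 1)) {
      n2 <- N - m
      for (k in 1:(N - 1)) {
        support <- max(0, k - n2):min(k, m)
        dens <- stats::dhyper(support, m, n2, k)
        for (a in support) {
          ours <- fisher_exact_2x2(c(a, k - a, m - a, n2 - k + a))
          oracle <- sum(dens[dens <= dens[match(a, support)] * (1 + 1e-7)])
          worst <- max(worst, abs(ours - oracle))
        }
      }
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("Fisher agrees with the classical implementation on random tables", {
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    expect_equal(fisher_exact_2x2(tab, "less"),
                 stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher handles the worked examples and degenerate margins", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(8, 2, 2, 8), 2, byrow = TRUE)),
               0.023014, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(c(0, 5, 0, 7)), 1)  # empty first column
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("BH adjustment matches the step-up formula and its invariances", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(limbdual:::adjust_p(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
})

test_that("ddct reproduces hand calculations and its invariances", {
  d <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 3),
    condition = rep(c("control", "treated"), each = 3),
    gene = rep(c("MYOG", "GAPDH", "RPS17"), 2),
    ct = c(25, 20, 22, 26, 20, 22)
  )
  out <- ddct(d)
  expect_equal(out$delta_ct, c(4, 5))  # 25 - mean(20, 22); 26 - 21
  expect_equal(out$relative_level, c(1, 0.5))  # ddCt 0 and 1

  # control condition normalised to 1 (geometric mean; exact per replicate
  # when control replicates share dCt)
  d2 <- dplyr::bind_rows(d, tibble::tibble(
    sample = "s3", condition = "control",
    gene = c("MYOG", "GAPDH", "RPS17"), ct = c(25.5, 20.5, 22.5)
  ))
  out2 <- ddct(d2)
  ctrl <- out2$relative_level[out2$condition == "control"]
  expect_equal(exp(mean(log(ctrl))), 1, tolerance = 1e-12)

  # invariance to a per-sample global Ct shift
  d3 <- d
  d3$ct <- d3$ct + rep(c(1.7, -0.4), each = 3)
  expect_equal(ddct(d3)$relative_level, out$relative_level)

  expect_error(ddct(d[d$gene != "GAPDH", ]), "reference")
  expect_error(ddct(d, control = "missing"), "control")
})
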