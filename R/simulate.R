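#' Configure the synthetic limb scRNA-seq generator
#'
#' Builds a validated simulation configuration describing a developing-limb
#' cell mixture: connective-tissue (CT) and muscle (M) populations, unrelated
#' "other" populations, a small transitional population whose expression moves
#' from the CT programme to the M programme along a latent pseudotime, planted
#' doublets, log-normal library-size variation, negative-binomial (NB)
#' over-dispersion and a subset of cells with an inflated mitochondrial
#' fraction as quality-control bait.
#'
#' Population names determine their role: names matching `CT`/`CT_*` carry the
#' CT marker and programme genes, `M`/`M_*` the myogenic ones, anything else is
#' an unrelated population with its own programme. Transitional cells
#' interpolate between the first CT-type and the first M-type population using
#' two logistic switches in pseudotime \eqn{t \in [0,1]} (steepness 10): the
#' muscle programme rises with midpoint 0.35 and, in `"late"` mode, the CT
#' programme falls with midpoint 0.65. In `"early"` mode the CT switch midpoint
#' lies beyond the sampled pseudotime range, so muscle markers are already up
#' while CT markers are not yet down -- the early-stage asymmetry.
#'
#' Rates are expressed as expected counts per unit of library size: a gene with
#' rate \eqn{r} in a cell with library size \eqn{L} has NB mean \eqn{rL}.
#'
#' @param n_cells Named integer vector: cells per (non-transitional, singlet)
#'   population. Default `c(CT = 1800, M = 1800, OTHER_1 = 700, OTHER_2 = 700)`.
#' @param n_genes_total Total number of genes, including markers, ID genes,
#'   per-population programme genes, mitochondrial genes and housekeeping fill.
#' @param marker_means Optional named list (population -> named numeric vector
#'   of gene -> rate) overriding default rates for specific genes.
#' @param dual_fraction Proportion of all singlet cells that are transitional.
#' @param doublet_rate Proportion of final barcodes that are doublets.
#' @param biphasic_mode `"late"` (both switches inside the trajectory) or
#'   `"early"` (muscle up, CT not yet down).
#' @param nb_dispersion NB size parameter (> 0); smaller = more over-dispersed.
#' @param libsize_mu,libsize_sigma Log-normal library-size parameters.
#' @param mito_gene_count Number of `MT-` prefixed mitochondrial genes.
#' @param mito_high_fraction Proportion of singlet cells whose mitochondrial
#'   rate share is inflated to ~0.30 of the transcriptome (QC bait).
#' @param panel [marker_panel()] whose genes are planted in the CT and M
#'   populations.
#' @param seed Integer seed; a fixed configuration (including seed) yields a
#'   byte-identical dataset.
#' @return A `sim_config` object; inspect `$gene_table` (tibble of gene roles)
#'   and `$rates` (genes x populations rate matrix).
#' @examples
#' cfg <- sim_config(n_cells = c(CT = 50, M = 50), dual_fraction = 0,
#'                   doublet_rate = 0, seed = 1)
#' cfg$gene_table
#' @export
sim_config <- function(n_cells = c(CT = 1800, M = 1800, OTHER_1 = 700, OTHER_2 = 700),
                       n_genes_total = 500,
                       marker_means = NULL,
                       dual_fraction = 0.04,
                       doublet_rate = 0.05,
                       biphasic_mode = c("late", "early"),
                       nb_dispersion = 2.0,
                       libsize_mu = log(5000),
                       libsize_sigma = 0.35,
                       mito_gene_count = 10,
                       mito_high_fraction = 0.05,
                       panel = marker_panel(),
                       seed = 1L) {
  biphasic_mode <- match.arg(biphasic_mode)
  if (is.null(names(n_cells)) || any(names(n_cells) == "")) {
    abort("n_cells must be a named vector of per-population cell counts")
  }
  if (any(n_cells < 0) || sum(n_cells) == 0) abort("population cell counts must be >= 0 and sum > 0")
  if (!.is_prop(dual_fraction)) abort("dual_fraction must be a proportion in [0, 1]")
  if (!is.numeric(doublet_rate) || doublet_rate < 0 || doublet_rate >= 1) {
    abort("doublet_rate must be in [0, 1)")
  }
  if (!.is_prop(mito_high_fraction)) abort("mito_high_fraction must be in [0, 1]")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (libsize_sigma < 0) abort("libsize_sigma must be >= 0")

  pops <- names(n_cells)
  if ("TRANSITIONAL" %in% pops) abort("'TRANSITIONAL' is a reserved population name")
  types <- .population_type(pops)
  if (dual_fraction > 0 && (!any(types == "CT") || !any(types == "M"))) {
    abort("dual_fraction > 0 requires at least one CT-type and one M-type population")
  }

  gt <- .build_gene_table(pops, types, panel, n_genes_total, mito_gene_count)
  rates <- .build_rates(gt, pops, types, panel)

  if (!is.null(marker_means)) {
    if (is.null(names(marker_means))) abort("marker_means must be a named list (population -> rates)")
    for (pop in names(marker_means)) {
      if (!pop %in% pops) abort(paste0("marker_means population not in n_cells: ", pop))
      ov <- marker_means[[pop]]
      .assert_genes_present(names(ov), gt$gene)
      rates[names(ov), pop] <- as.numeric(ov)
    }
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("configuration error: rates must be finite and non-negative")
  }

  structure(list(
    n_cells = n_cells, n_genes_total = n_genes_total,
    dual_fraction = dual_fraction, doublet_rate = doublet_rate,
    biphasic_mode = biphasic_mode, nb_dispersion = nb_dispersion,
    libsize_mu = libsize_mu, libsize_sigma = libsize_sigma,
    mito_gene_count = mito_gene_count, mito_high_fraction = mito_high_fraction,
    panel = panel, seed = as.integer(seed),
    gene_table = gt, rates = rates,
    id_genes = c("ID1", "ID2", "ID3"),
    id_rate_transitional = 0.002,
    switch_steepness = 10,
    switch_mid_m = 0.35,
    switch_mid_ct = if (biphasic_mode == "late") 0.65 else Inf,
    mito_high_share = 0.30
  ), class = "sim_config")
}

.population_type <- function(pops) {
  ifelse(grepl("^CT($|[_0-9])", pops), "CT",
         ifelse(grepl("^M($|[_0-9])", pops), "M", "OTHER"))
}

# Deterministic gene panel: paper markers, ID genes, 50 programme genes per
# population, MT- mitochondrial genes, housekeeping fill.
.build_gene_table <- function(pops, types, panel, n_genes_total, mito_gene_count) {
  n_prog <- 50L
  prog <- unlist(lapply(pops, function(p) sprintf("PRG-%s-%02d", p, seq_len(n_prog))))
  mito <- if (mito_gene_count > 0) sprintf("MT-G%02d", seq_len(mito_gene_count)) else character()
  fixed <- c(panel$ct_genes, panel$m_genes, c("ID1", "ID2", "ID3"), prog, mito)
  if (anyDuplicated(fixed)) abort("duplicate gene ids in panel/programme construction")
  n_hk <- n_genes_total - length(fixed)
  if (n_hk < 20) {
    abort(paste0("n_genes_total too small: need at least ", length(fixed) + 20, " genes"))
  }
  hk <- sprintf("HK-%04d", seq_len(n_hk))
  role <- c(
    rep("ct_marker", length(panel$ct_genes)),
    rep("m_marker", length(panel$m_genes)),
    rep("id", 3L),
    rep(paste0("program_", rep(pops, each = n_prog)), 1L),
    rep("mito", length(mito)),
    rep("housekeeping", n_hk)
  )
  tibble::tibble(gene = c(fixed, hk), role = role)
}

# Default per-unit-library rates. Housekeeping and programme rates span a
# log-scale range so variable-gene selection has structure to find.
.build_rates <- function(gt, pops, types, panel) {
  rates <- matrix(0, nrow = nrow(gt), ncol = length(pops),
                  dimnames = list(gt$gene, pops))
  r_marker <- 0.0012
  id_base <- 2e-04
  n_prog <- sum(gt$role == paste0("program_", pops[1]))
  prog_rates <- exp(seq(log(0.001), log(0.006), length.out = max(n_prog, 1)))
  hk_idx <- which(gt$role == "housekeeping")
  hk_rates <- exp(seq(log(5e-04), log(0.005), length.out = max(length(hk_idx), 1)))
  mito_idx <- which(gt$role == "mito")

  for (j in seq_along(pops)) {
    pop <- pops[j]
    if (types[j] == "CT") rates[panel$ct_genes, j] <- r_marker
    if (types[j] == "M") rates[panel$m_genes, j] <- r_marker
    rates[gt$role == "id", j] <- id_base
    rates[gt$role == paste0("program_", pop), j] <- prog_rates
    rates[hk_idx, j] <- hk_rates
    if (length(mito_idx) > 0) rates[mito_idx, j] <- 0.003
  }
  rates
}

# Logistic programme weights for transitional cells at pseudotime t.
.transitional_weights <- function(t, config) {
  list(
    ct = 1 - stats::plogis(config$switch_steepness * (t - config$switch_mid_ct)),
    m = stats::plogis(config$switch_steepness * (t - config$switch_mid_m))
  )
}

#' Simulate a limb-like scRNA-seq count dataset with ground truth
#'
#' Draws per-cell library sizes from a log-normal distribution and gene counts
#' from a negative binomial with mean `libsize x rate`, where rates are the
#' per-population rate vectors of the configuration. Transitional cells
#' interpolate CT marker/programme rates downward and muscle rates upward along
#' a uniform pseudotime via the configuration's logistic switches. A configured
#' fraction of singlets has its mitochondrial rate share inflated (total rate
#' preserved), and doublets are appended as raw sums of two distinct singlet
#' parents via [inject_doublets()].
#'
#' @param config A [sim_config()] object.
#' @return A `limb_dataset`: list with `counts` (sparse genes x cells integer
#'   matrix) and `truth` (tibble: `barcode`, `population`, `pseudotime`,
#'   `is_doublet`, `parent1`, `parent2`, `mito_high`).
#' @examples
#' ds <- simulate_counts(sim_config(n_cells = c(CT = 40, M = 40),
#'                                  dual_fraction = 0.1, doublet_rate = 0.05,
#'                                  seed = 7))
#' dim(ds$counts)
#' dplyr::count(ds$truth, population, is_doublet)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config object")
  set.seed(derive_seed(config$seed, "simulate"))

  pops <- names(config$n_cells)
  types <- .population_type(pops)
  n_base <- sum(config$n_cells)
  f <- config$dual_fraction
  n_trans <- if (f > 0) as.integer(round(f / (1 - f) * n_base)) else 0L
  pop_of_cell <- c(rep(pops, times = config$n_cells),
                   rep("TRANSITIONAL", n_trans))
  n_singlet <- length(pop_of_cell)
  barcodes <- sprintf("cell_%06d", seq_len(n_singlet))

  # RNG draws in fixed order: library sizes, pseudotimes, mito flags, counts
  libsize <- rlnorm(n_singlet, config$libsize_mu, config$libsize_sigma)
  pseudotime <- rep(NA_real_, n_singlet)
  if (n_trans > 0) pseudotime[pop_of_cell == "TRANSITIONAL"] <- runif(n_trans)
  mito_high <- runif(n_singlet) < config$mito_high_fraction

  # per-cell rate matrix (genes x cells)
  rate_mat <- matrix(0, nrow = nrow(config$gene_table), ncol = n_singlet,
                     dimnames = list(config$gene_table$gene, NULL))
  for (j in seq_along(pops)) {
    idx <- which(pop_of_cell == pops[j])
    if (length(idx) > 0) rate_mat[, idx] <- config$rates[, pops[j]]
  }
  if (n_trans > 0) {
    idx <- which(pop_of_cell == "TRANSITIONAL")
    ct_pop <- pops[which(types == "CT")[1]]
    m_pop <- pops[which(types == "M")[1]]
    base <- matrix(config$rates[, ct_pop], nrow = nrow(rate_mat), ncol = n_trans)
    rownames(base) <- rownames(rate_mat)
    w <- .transitional_weights(pseudotime[idx], config)
    gt <- config$gene_table
    ct_rows <- gt$role %in% c("ct_marker", paste0("program_", ct_pop))
    # in early mode only the myogenic marker factors rise; the broad muscle
    # programme has not yet engaged, so CT expression is not diluted
    m_rows <- if (config$biphasic_mode == "early") gt$role == "m_marker" else
      gt$role %in% c("m_marker", paste0("program_", m_pop))
    base[ct_rows, ] <- config$rates[ct_rows, ct_pop] %o% w$ct
    base[m_rows, ] <- config$rates[m_rows, m_pop] %o% w$m
    base[gt$role == "id", ] <- config$id_rate_transitional
    rate_mat[, idx] <- base
  }

  # inflate the mitochondrial share for flagged cells, preserving total rate
  mito_rows <- config$gene_table$role == "mito"
  if (any(mito_rows) && any(mito_high)) {
    for (i in which(mito_high)) {
      s_tot <- sum(rate_mat[, i])
      s_mito <- sum(rate_mat[mito_rows, i])
      if (s_mito > 0 && s_mito < s_tot) {
        share <- config$mito_high_share
        rate_mat[mito_rows, i] <- rate_mat[mito_rows, i] * (share * s_tot / s_mito)
        rate_mat[!mito_rows, i] <- rate_mat[!mito_rows, i] *
          ((1 - share) * s_tot / (s_tot - s_mito))
      }
    }
  }

  mu <- sweep(rate_mat, 2, libsize, `*`)
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = config$nb_dispersion),
    nrow = nrow(mu), dimnames = list(rownames(rate_mat), barcodes)
  )
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")

  truth <- tibble::tibble(
    barcode = barcodes,
    population = pop_of_cell,
    pseudotime = pseudotime,
    is_doublet = FALSE,
    parent1 = NA_character_,
    parent2 = NA_character_,
    mito_high = mito_high
  )
  ds <- structure(list(counts = counts, truth = truth), class = "limb_dataset")
  if (config$doublet_rate > 0) {
    ds <- inject_doublets(ds, rate = config$doublet_rate,
                          seed = derive_seed(config$seed, "doublet_inject"))
  }
  ds
}

#' Append planted doublets to a dataset
#'
#' Appends `ceiling(rate * n_final)` barcodes, each the elementwise sum of the
#' raw counts of two distinct randomly chosen singlet parents, so that
#' `n_final = n_singlets / (1 - rate)`. Raw sums are deliberately not rescaled:
#' real doublets carry an elevated library size, and downstream stages must
#' cope with (or exploit) it.
#'
#' @param dataset A `limb_dataset` (list with `counts` and `truth`).
#' @param rate Proportion of final barcodes that are doublets, in `[0, 1)`.
#' @param seed Integer seed for parent sampling.
#' @return The dataset with doublet columns appended and truth rows recording
#'   `is_doublet = TRUE` and the two parent barcodes.
#' @export
inject_doublets <- function(dataset, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(dataset)
  counts <- dataset$counts
  truth <- dataset$truth
  singlet <- which(!truth$is_doublet)
  if (length(singlet) < 2) abort("need at least 2 singlets to form doublets")
  n_s <- length(singlet)
  n_d <- as.integer(ceiling(rate * n_s / (1 - rate)))
  set.seed(seed)
  p1 <- sample(singlet, n_d, replace = TRUE)
  p2 <- vapply(p1, function(i) sample(setdiff(singlet, i), 1L), integer(1))
  dbl <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(dbl) <- sprintf("cell_%06d", ncol(counts) + seq_len(n_d))
  new_truth <- tibble::tibble(
    barcode = colnames(dbl),
    population = NA_character_,
    pseudotime = NA_real_,
    is_doublet = TRUE,
    parent1 = truth$barcode[p1],
    parent2 = truth$barcode[p2],
    mito_high = NA
  )
  structure(list(
    counts = cbind(counts, dbl),
    truth = dplyr::bind_rows(truth, new_truth)
  ), class = "limb_dataset")
}

#' @export
print.limb_dataset <- function(x, ...) {
  cat("<limb_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n", sep = "")
  tab <- table(ifelse(x$truth$is_doublet, "DOUBLET", x$truth$population))
  cat("  populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
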