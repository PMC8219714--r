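# Self-contained implementations of the test statistics the workflow relies
# on: Wilcoxon rank-sum, Fisher exact, Benjamini-Hochberg and 2^-ddCt.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks handle ties. For `min(|x|, |y|) >= 8` the p-value uses the normal
#' approximation with tie-corrected variance and a 0.5 continuity correction;
#' for smaller samples the exact null distribution is obtained by enumerating
#' all assignments of the pooled values (two-sided p = `min(1, 2 * min(lower,
#' upper))`). Enumeration is skipped in favour of the normal approximation in
#' the degenerate case where the smaller group is tiny but the other is so
#' large that the assignment count is astronomical (> 1e6 subsets).
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (x versus y).
#' @return List with `statistic` (Mann-Whitney U for x), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by full enumeration
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U for x

  if (length(unique(pooled)) == 1) {
    return(list(statistic = u, p = 1, method = "degenerate"))
  }

  use_exact <- min(nx, ny) < 8 && choose(n, min(nx, ny)) <= 1e6
  if (use_exact) {
    m <- min(nx, ny)
    sums <- colSums(combn(r, m))
    # U of the smaller group under each assignment
    u_small <- sums - m * (m + 1) / 2
    u_obs <- if (nx <= ny) u else nx * ny - u  # U of smaller group observed
    eps <- 1e-9
    p_le <- mean(u_small <= u_obs + eps)
    p_ge <- mean(u_small >= u_obs - eps)
    # translate small-group tails back to x tails
    if (nx <= ny) {
      p_less <- p_le; p_greater <- p_ge
    } else {
      p_less <- p_ge; p_greater <- p_le
    }
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less,
                greater = p_greater)
    return(list(statistic = u, p = p, method = "exact"))
  }

  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1, method = "degenerate"))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
              two_sided = (u - mu - sign(u - mu) * 0.5) / sigma,
              greater = (u - mu - 0.5) / sigma,
              less = (u - mu + 0.5) / sigma)
  p <- switch(alternative,
              two_sided = min(1, 2 * pnorm(-abs(z))),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(statistic = u, p = p, method = "normal")
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric enumeration with all margins fixed. The two-sided p-value is
#' the sum of the probabilities of tables no more probable than the observed
#' one (relative tolerance 1e-7 for ties). Probabilities are computed from
#' log-binomial coefficients directly.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows: expressing/not, columns: group1/group2), or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (association of
#'   the top-left cell).
#' @return The p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))  # ~0.0230
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2, 2))) abort("tab must be 2x2")
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  } else {
    if (length(tab) != 4) abort("tab must be a 2x2 matrix or length-4 vector")
    a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  }
  cells <- c(a, b, cc, d)
  if (any(cells < 0) || any(cells != round(cells))) abort("cells must be non-negative integers")
  m <- a + cc      # column 1 total
  n2 <- b + d      # column 2 total
  k <- a + b       # row 1 total
  if (m + n2 == 0 || k == 0 || k == m + n2 || m == 0 || n2 == 0) return(1)

  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  i_obs <- match(a, support)
  p_obs <- probs[i_obs]
  switch(alternative,
         less = sum(probs[support <= a]),
         greater = sum(probs[support >= a]),
         two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the step-up adjusted values `min_k>=i (p_(k) * m / k)` capped at 1,
#' in the original input order. Adjusted values are always >= raw values and
#' monotone non-decreasing in rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA not allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

# p-value adjustment dispatcher: the workflow's config exposes bh | bonferroni.
adjust_p <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (method == "bh") benjamini_hochberg(p) else pmin(1, p * length(p))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, dCt = Ct(target) - mean(Ct of reference genes); ddCt =
#' dCt - mean(dCt over control-condition samples) per target gene; the relative
#' level is `2^-ddCt`. The control condition is thereby normalised to 1 (its
#' geometric mean level is exactly 1, and so is every control sample when
#' control replicates share the same dCt). Adding a constant to every Ct of a
#' sample leaves its relative levels unchanged.
#'
#' @param data Long-format data frame with columns `sample`, `condition`,
#'   `gene`, `ct` (one row per sample x gene Ct measurement).
#' @param reference_genes Reference (normalizer) gene names, default GAPDH and
#'   RPS17; every sample must have a Ct for each.
#' @param control Condition label used as the calibrator (default "control").
#' @return Tibble (`sample`, `condition`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `relative_level`) for every non-reference gene.
#' @examples
#' d <- tibble::tibble(
#'   sample = rep(c("s1", "s2"), each = 3),
#'   condition = rep(c("control", "treated"), each = 3),
#'   gene = rep(c("MYOG", "GAPDH", "RPS17"), 2),
#'   ct = c(25, 20, 22, 26, 20, 22)
#' )
#' ddct(d)
#' @export
ddct <- function(data, reference_genes = c("GAPDH", "RPS17"), control = "control") {
  data <- tibble::as_tibble(data)
  needed <- c("sample", "condition", "gene", "ct")
  if (!all(needed %in% names(data))) {
    abort(paste0("data must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyNA(data$ct) || any(!is.finite(data$ct))) abort("Ct values must be finite")
  if (length(reference_genes) < 1) abort("at least one reference gene is required")
  if (!control %in% data$condition) abort(paste0("control condition not present: ", control))

  refs <- data |>
    dplyr::filter(.data$gene %in% reference_genes) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ref_ct = mean(.data$ct), n_ref = dplyr::n(), .groups = "drop")
  if (any(refs$n_ref < length(reference_genes)) ||
      !all(unique(data$sample) %in% refs$sample)) {
    abort("every sample needs a Ct for each reference gene")
  }

  targets <- data |>
    dplyr::filter(!.data$gene %in% reference_genes) |>
    dplyr::left_join(refs[, c("sample", "ref_ct")], by = "sample") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct)
  calib <- targets |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(control_delta_ct = mean(.data$delta_ct), .groups = "drop")
  targets |>
    dplyr::left_join(calib, by = "gene") |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct - .data$control_delta_ct,
                  relative_level = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("sample", "condition", "gene", "delta_ct", "delta_delta_ct",
                  "relative_level")
}
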