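# Internal helpers shared across stages.

# Stage offsets for deriving per-stage seeds from the single user seed.
# Keeping everything below 2^31 - 1 so seeds stay valid R integers.
.stage_offsets <- c(
  simulate = 1L, doublet_inject = 2L, doublet_sim = 3L, doublet_embed = 4L,
  cluster = 5L, module_ct = 6L, module_m = 7L, annotate = 8L, benchmark = 9L
)

#' Derive a per-stage seed from a global seed
#'
#' Stages that consume randomness each draw their own seed from the single
#' pipeline seed through a fixed affine counter scheme, so that rerunning one
#' stage in isolation reproduces exactly what the full pipeline did.
#'
#' @param seed Integer global seed.
#' @param stage Stage name, one of `names(limbdual:::.stage_offsets)`, or an
#'   integer counter.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stage) {
  offset <- if (is.character(stage)) {
    if (!stage %in% names(.stage_offsets)) abort(paste0("unknown stage: ", stage))
    .stage_offsets[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer(((as.double(seed) %% 2147483647) * 7919 + offset) %% 2147483646)
}

# Area under the ROC curve via the rank formulation (equivalent to the
# Mann-Whitney statistic scaled to [0, 1]). `score` may contain Inf.
auroc <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)  # midranks handle ties, including tied Inf
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Column sums / nonzero counts for a genes x cells sparse matrix, by a
# logical row mask. Faster than subsetting for repeated marker queries.
.col_any_positive <- function(mat, rows) {
  sub <- mat[rows, , drop = FALSE]
  Matrix::colSums(sub > 0) > 0
}

.assert_genes_present <- function(genes, available, what = "gene") {
  missing <- setdiff(genes, available)
  if (length(missing) > 0) {
    abort(paste0(
      "missing ", what, if (length(missing) > 1) "s" else "", ": ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

.is_prop <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

# timestamped progress line on stderr
.log_stage <- function(verbose, ...) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  }
  invisible(NULL)
}
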