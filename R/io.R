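#' Write a dataset to a 10x-style directory
#'
#' Emits the standard triplet layout: `matrix.mtx` (Matrix-Market coordinate
#' format, genes as rows, 1-based indices on disk), `features.tsv`
#' (`gene_id<TAB>gene_name`, no header), `barcodes.tsv` (one barcode per line)
#' and, when ground truth is present, `truth.tsv` (tab-separated with a header
#' row). Writing the same dataset twice produces byte-identical files.
#'
#' @param dataset A `limb_dataset` (or any list with a sparse integer `counts`
#'   matrix and optionally a `truth` tibble).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- dataset$counts
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(gene_id = rownames(counts), gene_name = rownames(counts)),
    file.path(dir, "features.tsv"), col_names = FALSE
  )
  readr::write_tsv(tibble::tibble(barcode = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  if (!is.null(dataset$truth)) {
    readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"), col_names = TRUE)
  }
  invisible(dir)
}

#' Read a dataset from a 10x-style directory
#'
#' Parses the triplet layout written by [write_dataset()] (or exported by
#' standard single-cell tools): Matrix-Market `matrix.mtx` with genes as rows,
#' `features.tsv`, `barcodes.tsv` and an optional `truth.tsv`. Validates that
#' matrix dimensions match the feature and barcode tables, that all entries are
#' non-negative integers, and that ids are unique. The gene name `MYOD` is
#' accepted as an alias of `MYOD1`.
#'
#' @param dir Directory containing the files.
#' @return A `limb_dataset` (list with `counts` and, if present, `truth`).
#' @export
read_dataset <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  for (f in c(mtx_path, file.path(dir, c("features.tsv", "barcodes.tsv")))) {
    if (!file.exists(f)) abort(paste0("format error: missing file ", f))
  }
  counts <- tryCatch(
    Matrix::readMM(mtx_path),
    error = function(e) abort(paste0("format error in ", mtx_path, ": ", conditionMessage(e)))
  )
  feats <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = c("gene_id", "gene_name"),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  bcs <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(feats) != nrow(counts)) {
    abort(sprintf("format error: features.tsv has %d rows but matrix declares %d gene rows",
                  nrow(feats), nrow(counts)))
  }
  if (nrow(bcs) != ncol(counts)) {
    abort(sprintf("format error: barcodes.tsv has %d rows but matrix declares %d cell columns",
                  nrow(bcs), ncol(counts)))
  }
  x <- counts@x
  if (length(x) > 0) {
    bad <- which(x != round(x) | x < 0)
    if (length(bad) > 0) {
      abort(sprintf("format error: non-integer or negative count (entry %d, value %s)",
                    bad[1], format(x[bad[1]])))
    }
  }
  genes <- feats$gene_name
  genes[genes == "MYOD"] <- "MYOD1"  # accepted alias
  if (anyDuplicated(genes)) abort("format error: duplicate gene ids in features.tsv")
  if (anyDuplicated(bcs$barcode)) abort("format error: duplicate barcodes in barcodes.tsv")
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(genes, bcs$barcode)

  truth <- NULL
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    truth <- readr::read_tsv(truth_path, col_types = readr::cols(
      barcode = readr::col_character(), population = readr::col_character(),
      pseudotime = readr::col_double(), is_doublet = readr::col_logical(),
      parent1 = readr::col_character(), parent2 = readr::col_character(),
      mito_high = readr::col_logical()
    ), progress = FALSE)
    if (!setequal(truth$barcode, bcs$barcode)) {
      abort("format error: truth.tsv barcodes do not match barcodes.tsv")
    }
  }
  structure(list(counts = counts, truth = truth), class = "limb_dataset")
}
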