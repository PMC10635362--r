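# Thin readers/writers for the standard on-disk exchange formats:
# Matrix Market counts with genes/barcodes sidecars, and TSV tables.

#' Write a counts matrix as Matrix Market plus gene/barcode sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, and `barcodes.tsv` into `dir`.
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a counts matrix written by [write_counts_mtx()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Sparse genes x cells matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write / read a tab-separated table
#'
#' Plain-text TSV with a header row; the exchange format for metadata,
#' cohort, mutation, evidence, and score tables.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
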