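#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`)
#' in `dir`. Features files may have one column (gene name) or the 10x
#' two/three-column layout (id, name, type); the second column is used as the
#' gene name when present.
#'
#' @param dir directory containing the triplet.
#' @return gene x cell `dgCMatrix` with dimnames set.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- readLines(bc)
  feats <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts gene x cell matrix (dense or sparse).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(rownames(counts), rownames(counts),
                         "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense gene x cell count matrix from TSV
#'
#' First column = gene names, header row = cell barcodes.
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read / write cell assignment tables
#'
#' @param x data.frame from [classify_cells] (optionally with QC columns).
#' @param path TSV file path.
#' @return `read_cells_tsv` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_cells_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
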