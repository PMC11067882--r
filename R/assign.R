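# Per-cell number of TFs at or above a UMI threshold, from a long
# (cell_barcode, tf_name, n_umis) table. Returns a named integer vector over
# `cells`.
.tfs_at_threshold <- function(table, threshold, cells) {
  sub <- table[table$n_umis >= threshold, , drop = FALSE]
  k <- integer(length(cells))
  names(k) <- cells
  if (nrow(sub)) {
    t0 <- tapply(sub$tf_name, sub$cell_barcode,
                 function(x) length(unique(x)))
    k[names(t0)] <- as.integer(t0)
  }
  k
}

#' Sweep minimum-UMI thresholds for single-iTF detection
#'
#' Because each cell line carries a single inducible TF, a cell should show
#' exactly one iTF; ambient contamination and library artefacts add spurious
#' low-UMI assignments. For each candidate threshold the cells with exactly
#' one TF at or above the threshold ("single"), two or more ("multi"), and
#' none ("zero") are counted.
#'
#' @param table UMI count table from [umi_count_table] (columns
#'   `cell_barcode`, `tf_name`, `n_umis`).
#' @param thresholds integer thresholds to sweep (default 1..5).
#' @return data.frame with columns `threshold`, `n_single`, `n_multi`,
#'   `n_zero`.
#' @export
sweep_umi_thresholds <- function(table, thresholds = 1:5) {
  if (nrow(table) == 0) stop("EmptyTable: no UMI counts", call. = FALSE)
  cells <- unique(table$cell_barcode)
  out <- data.frame(threshold = as.integer(thresholds),
                    n_single = NA_integer_, n_multi = NA_integer_,
                    n_zero = NA_integer_)
  for (i in seq_along(thresholds)) {
    k <- .tfs_at_threshold(table, thresholds[i], cells)
    out$n_single[i] <- sum(k == 1L)
    out$n_multi[i] <- sum(k >= 2L)
    out$n_zero[i] <- sum(k == 0L)
  }
  out
}

#' Select the minimum-UMI threshold maximizing single-iTF cells
#'
#' @param sweep output of [sweep_umi_thresholds].
#' @return the threshold with the largest `n_single`; ties broken toward the
#'   smallest threshold.
#' @export
select_threshold <- function(sweep) {
  sweep <- sweep[order(sweep$threshold), , drop = FALSE]
  sweep$threshold[which.max(sweep$n_single)]
}

#' Classify cells by iTF content
#'
#' A cell is `single` if exactly one TF reaches the threshold, `multi` if two
#' or more do, `control` if it has zero iTF UMIs at any level, and
#' `unassigned` if it carries sub-threshold iTF evidence only (such cells are
#' neither confidently perturbed nor clean controls).
#'
#' @param table UMI count table (long form).
#' @param threshold minimum UMI count for an iTF call.
#' @param all_cells optional character vector of every cell barcode in the
#'   experiment; barcodes absent from `table` have no iTF UMIs and are
#'   labelled `control`.
#' @return data.frame with columns `cell_barcode`, `label`, `tf_name`
#'   (non-NA only for `single` cells).
#' @export
classify_cells <- function(table, threshold, all_cells = NULL) {
  stopifnot(threshold >= 1)
  cells <- unique(c(table$cell_barcode, all_cells))
  k <- .tfs_at_threshold(table, threshold, cells)
  tot <- integer(length(cells)); names(tot) <- cells
  if (nrow(table)) {
    t0 <- tapply(table$n_umis, table$cell_barcode, sum)
    tot[names(t0)] <- as.integer(t0)
  }
  label <- ifelse(k == 1L, "single",
           ifelse(k >= 2L, "multi",
           ifelse(tot == 0L, "control", "unassigned")))
  tf <- rep(NA_character_, length(cells))
  if (any(k == 1L)) {
    sub <- table[table$n_umis >= threshold, , drop = FALSE]
    singles <- names(k)[k == 1L]
    m <- sub[match(singles, sub$cell_barcode), "tf_name"]
    tf[match(singles, cells)] <- m
  }
  data.frame(cell_barcode = cells, label = label, tf_name = tf,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell quality-control criteria
#'
#' All comparisons are strict: a cell passes with more than `min_genes`
#' detected genes, less than `max_mito_fraction` of its counts from
#' mitochondrial genes, and more than `min_molecules` total molecules.
#'
#' @param min_genes minimum unique detected genes (exclusive bound).
#' @param max_mito_fraction maximum mitochondrial count fraction (exclusive).
#' @param min_molecules minimum total molecules (exclusive bound).
#' @return list of class `qc_criteria`.
#' @export
qc_criteria <- function(min_genes = 1000, max_mito_fraction = 0.10,
                        min_molecules = 10000) {
  stopifnot(min_genes > 0, max_mito_fraction > 0, min_molecules > 0)
  structure(list(min_genes = min_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_molecules = min_molecules),
            class = "qc_criteria")
}

#' Apply cell quality control to a count matrix
#'
#' @param counts gene x cell count matrix (dense or `dgCMatrix`), with gene
#'   names as rownames and cell barcodes as colnames.
#' @param criteria a [qc_criteria] object.
#' @param mito_genes character vector of mitochondrial gene names; by default
#'   genes whose name starts with `"mt-"` (mouse convention).
#' @return data.frame per cell: `cell_barcode`, `n_genes`, `total_counts`,
#'   `mito_fraction`, `qc_pass`; the pass fraction is attached as the
#'   `"qc_summary"` attribute.
#' @export
qc_filter_cells <- function(counts, criteria = qc_criteria(),
                            mito_genes = NULL) {
  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(counts), value = TRUE)
  mito_genes <- intersect(mito_genes, rownames(counts))
  if (length(mito_genes) == 0)
    warning("UnknownMitoGenes: no mitochondrial genes matched; ",
            "mito fraction set to 0", call. = FALSE)
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito / total, 0)
  pass <- (n_genes > criteria$min_genes) &
    (mito_frac < criteria$max_mito_fraction) &
    (total > criteria$min_molecules)
  out <- data.frame(cell_barcode = colnames(counts),
                    n_genes = as.integer(n_genes),
                    total_counts = as.numeric(total),
                    mito_fraction = as.numeric(mito_frac),
                    qc_pass = as.logical(pass),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "qc_summary") <- list(n_cells = nrow(out),
                                  n_pass = sum(out$qc_pass),
                                  pass_fraction = mean(out$qc_pass))
  out
}
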