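#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Filter a gene-set collection against a matrix and exclusion lists
#'
#' Removes the induced-TF genes (and optionally ribosomal genes) from every
#' set, intersects with the genes present in the matrix, and drops sets with
#' fewer than `min_size` genes remaining.
#'
#' @param sets named list of gene vectors (see [read_gmt]).
#' @param genes gene names available in the expression matrix.
#' @param itf_genes induced-TF gene names, removed from every set.
#' @param ribosomal_genes additional exclusion list; `NULL` to skip,
#'   `"prefix"` to exclude genes starting with `Rps`/`Rpl` (mouse naming).
#' @param min_size minimum retained set size (default 15).
#' @return named list of filtered sets; dropped set names are attached as the
#'   `"dropped_sets"` attribute.
#' @export
filter_gene_sets <- function(sets, genes, itf_genes = character(0),
                             ribosomal_genes = NULL, min_size = 15L) {
  if (identical(ribosomal_genes, "prefix"))
    ribosomal_genes <- grep("^Rp[sl]", genes, value = TRUE)
  excl <- union(itf_genes, ribosomal_genes)
  flt <- lapply(sets, function(g) setdiff(intersect(unique(g), genes), excl))
  keep <- vapply(flt, length, integer(1)) >= min_size
  if (any(!keep))
    message("SetTooSmall: dropped ", sum(!keep), " gene set(s) below ",
            min_size, " genes")
  out <- flt[keep]
  attr(out, "dropped_sets") <- names(flt)[!keep]
  out
}

#' Gene-set-restricted differentiation indexes
#'
#' Repeats the whole index pipeline (normalize, restrict to the set's genes,
#' PCA, control-referenced z-distance) for each gene set, and tabulates the
#' per-TF median index per set.
#'
#' @param counts gene x cell count matrix (or an already normalized matrix
#'   with `normalize_method = "none"`).
#' @param sets named list of gene sets (already parsed; filtering against the
#'   matrix, the iTF list and `min_size` is applied here).
#' @param control_cells control cell barcodes.
#' @param labels optional cell assignments from [classify_cells]; when given,
#'   per-(TF, set) medians are computed over single-iTF cells (plus a
#'   `control` row).
#' @param itf_genes induced-TF gene names, excluded from every set and from
#'   the PCA.
#' @param ribosomal_genes see [filter_gene_sets].
#' @param n_pcs PCs per set (default 50, capped per set at feasible rank).
#' @param min_size minimum set size after exclusions (default 15).
#' @param normalize_method see [normalize_counts].
#' @return list with `index` (cell x set matrix of differentiation indexes),
#'   `medians` (group x set matrix when `labels` given, else `NULL`), and
#'   `dropped_sets`.
#' @export
geneset_indexes <- function(counts, sets, control_cells, labels = NULL,
                            itf_genes = character(0), ribosomal_genes = NULL,
                            n_pcs = 50L, min_size = 15L,
                            normalize_method = "log1p_cp10k") {
  norm <- normalize_counts(counts, method = normalize_method)
  flt <- filter_gene_sets(sets, rownames(norm), itf_genes, ribosomal_genes,
                          min_size)
  if (length(flt) == 0) stop("no gene set survived filtering", call. = FALSE)
  idx <- matrix(NA_real_, ncol(norm), length(flt),
                dimnames = list(colnames(norm), names(flt)))
  for (s in names(flt)) {
    sub <- norm[flt[[s]], , drop = FALSE]
    k <- min(n_pcs, length(flt[[s]]))
    di <- differentiation_index(sub, control_cells, n_pcs = k)
    idx[names(di$index), s] <- di$index
  }
  med <- NULL
  if (!is.null(labels)) {
    singles <- labels[labels$label == "single" & !is.na(labels$tf_name), ,
                      drop = FALSE]
    groups <- split(singles$cell_barcode, singles$tf_name)
    groups$control <- intersect(control_cells, rownames(idx))
    med <- do.call(rbind, lapply(groups, function(cells) {
      apply(idx[intersect(cells, rownames(idx)), , drop = FALSE], 2L, median)
    }))
    dimnames(med) <- list(names(groups), colnames(idx))
  }
  list(index = idx, medians = med,
       dropped_sets = attr(flt, "dropped_sets"))
}

#' TF similarity from gene-set index profiles
#'
#' Each TF is represented by its vector of median differentiation indexes
#' across gene sets; similarity is the correlation of those vectors, and TFs
#' are ordered by hierarchical clustering on distance `1 - similarity`.
#'
#' @param median_matrix TF x gene-set matrix of median indexes.
#' @param method correlation method (default `"pearson"`).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @return list with `similarity` (symmetric, unit diagonal), `hclust`, and
#'   `order` (TF names in dendrogram order).
#' @export
tf_similarity <- function(median_matrix, method = "pearson",
                          linkage = "average") {
  m <- as.matrix(median_matrix)
  if (ncol(m) < 2) stop("need >= 2 gene sets per TF", call. = FALSE)
  v <- apply(m, 1L, sd)
  if (any(v == 0 | !is.finite(v))) {
    warning("ZeroVarianceRow: dropped ", sum(v == 0 | !is.finite(v)),
            " TF row(s) with no variance across sets", call. = FALSE)
    m <- m[v > 0 & is.finite(v), , drop = FALSE]
  }
  if (nrow(m) < 2) stop("fewer than 2 TFs with variance", call. = FALSE)
  s <- cor(t(m), method = method)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  hc <- hclust(as.dist(1 - s), method = linkage)
  list(similarity = s, hclust = hc, order = rownames(s)[hc$order])
}
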