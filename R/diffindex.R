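#' Normalize a count matrix
#'
#' Default method: per-cell scaling to `scale_factor` total counts followed by
#' `log(1 + x)` ("log1p_cp10k"). Any normalization honouring the same
#' contract can be plugged in by passing a function, or a pre-normalized
#' matrix can be used downstream directly (`method = "none"`).
#'
#' @param counts gene x cell matrix of non-negative counts.
#' @param method `"log1p_cp10k"`, `"none"`, or a function
#'   `f(counts) -> matrix` of the same shape.
#' @param scale_factor per-cell library size target (default 10,000).
#' @return normalized gene x cell matrix; the method tag is attached as the
#'   `"normalization"` attribute.
#' @export
normalize_counts <- function(counts, method = "log1p_cp10k",
                             scale_factor = 1e4) {
  if (is.function(method)) {
    out <- method(counts)
    attr(out, "normalization") <- "custom"
    return(out)
  }
  method <- match.arg(method, c("log1p_cp10k", "none"))
  if (method == "none") {
    out <- as.matrix(counts)
    attr(out, "normalization") <- "none"
    return(out)
  }
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning("AllZeroCell: ", sum(zero), " cell(s) have zero total counts",
            call. = FALSE)
    tot[zero] <- 1  # leaves the all-zero column as zeros
  }
  out <- log1p(sweep(m, 2L, scale_factor / tot, `*`))
  attr(out, "normalization") <- "log1p_cp10k"
  out
}

#' Principal component analysis of normalized expression
#'
#' Genes are centred and cells are projected onto the top principal
#' components. The decomposition uses the symmetric eigendecomposition of the
#' smaller-dimension covariance (gene-gene) or Gram (cell-cell) matrix,
#' which is fast for typical screen cohorts. The induced-TF genes are
#' excluded before fitting so the ectopic transcript itself cannot drive the
#' embedding.
#'
#' @param norm gene x cell normalized matrix (see [normalize_counts]).
#' @param n_pcs number of components to keep (default 50, capped at the
#'   feasible rank with a warning).
#' @param exclude_genes gene names to drop before fitting (e.g. the iTF
#'   list).
#' @param center centre genes before decomposition (default TRUE; the index
#'   assumes centred data).
#' @return object of class `pc_space`: list with `scores` (cell x PC),
#'   `loadings` (gene x PC, orthonormal columns), `sdev`, `center`,
#'   `n_pcs`, `excluded_genes`.
#' @export
fit_pca <- function(norm, n_pcs = 50L, exclude_genes = NULL, center = TRUE) {
  m <- as.matrix(norm)
  if (!is.null(exclude_genes)) {
    keep <- !(rownames(m) %in% exclude_genes)
    m <- m[keep, , drop = FALSE]
  }
  x <- t(m)                                   # cells x genes
  n <- nrow(x); p <- ncol(x)
  mu <- if (center) colMeans(x) else rep(0, p)
  xc <- sweep(x, 2L, mu, `-`)
  rank_max <- min(n - as.integer(center), p)
  k <- as.integer(n_pcs)
  if (k > rank_max) {
    warning("RankDeficient: n_pcs reduced from ", k, " to ", rank_max,
            call. = FALSE)
    k <- rank_max
  }
  if (p <= n) {
    cv <- crossprod(xc) / (n - 1)
    ev <- eigen(cv, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    pos <- sum(lam > max(lam[1], 0) * 1e-12)
    k <- min(k, pos)
    loadings <- ev$vectors[, seq_len(k), drop = FALSE]
    scores <- xc %*% loadings
  } else {
    g <- tcrossprod(xc) / (n - 1)
    ev <- eigen(g, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    pos <- sum(lam > max(lam[1], 0) * 1e-12)
    k <- min(k, pos)
    u <- ev$vectors[, seq_len(k), drop = FALSE]
    d <- sqrt(lam[seq_len(k)] * (n - 1))
    scores <- sweep(u, 2L, d, `*`)
    loadings <- crossprod(xc, sweep(u, 2L, 1 / d, `*`))
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 sdev = sqrt(lam[seq_len(k)]), center = mu, n_pcs = k,
                 excluded_genes = exclude_genes),
            class = "pc_space")
}

#' @method print pc_space
#' @export
print.pc_space <- function(x, ...) {
  cat("PC space:", nrow(x$scores), "cells x", x$n_pcs, "PCs (",
      length(x$excluded_genes), "genes excluded before fitting )\n")
  invisible(x)
}

#' Differentiation index: control-referenced PC-space distance
#'
#' Quantifies how far each cell's transcriptome has moved from the
#' undifferentiated (control) state. The centroid of control cells in PC
#' space is computed; Euclidean distances of control cells to the centroid
#' give the reference mean `mu` and standard deviation `sigma` (sample
#' convention); every cell's index is its z-normalised distance
#' `(||s_i - c|| - mu) / sigma`. Control indexes therefore have mean 0 and
#' standard deviation 1 by construction, and a large positive index marks a
#' transcriptome departing the control state.
#'
#' @param x a `pc_space` from [fit_pca], or a gene x cell normalized matrix
#'   (PCA is then fitted internally with `n_pcs` and `exclude_genes`).
#' @param control_cells character vector of control cell barcodes (must match
#'   score rownames); at least 3 required.
#' @param n_pcs,exclude_genes passed to [fit_pca] when `x` is a matrix.
#' @return object of class `diff_index`: list with `index` (named per-cell
#'   vector), `reference` (list `centroid`, `mu`, `sigma`),
#'   `control_cells`, `n_pcs`.
#' @export
differentiation_index <- function(x, control_cells, n_pcs = 50L,
                                  exclude_genes = NULL) {
  pcs <- if (inherits(x, "pc_space")) x else
    fit_pca(x, n_pcs = n_pcs, exclude_genes = exclude_genes)
  s <- pcs$scores
  ctrl <- intersect(control_cells, rownames(s))
  if (length(ctrl) < 3)
    stop("DegenerateControls: need >= 3 control cells with scores, got ",
         length(ctrl), call. = FALSE)
  centroid <- colMeans(s[ctrl, , drop = FALSE])
  dist_all <- sqrt(rowSums(sweep(s, 2L, centroid, `-`)^2))
  mu <- mean(dist_all[ctrl])
  sigma <- sd(dist_all[ctrl])
  if (!is.finite(sigma) || sigma <= 0)
    stop("DegenerateControls: control distances have zero spread",
         call. = FALSE)
  structure(list(index = (dist_all - mu) / sigma,
                 reference = list(centroid = centroid, mu = mu,
                                  sigma = sigma),
                 control_cells = ctrl, n_pcs = pcs$n_pcs),
            class = "diff_index")
}

#' @method print diff_index
#' @export
print.diff_index <- function(x, ...) {
  cat("Differentiation index over", length(x$index), "cells (",
      length(x$control_cells), "controls,", x$n_pcs, "PCs )\n")
  cat("  control distance reference: mu =",
      format(x$reference$mu, digits = 4), ", sigma =",
      format(x$reference$sigma, digits = 4), "\n")
  cat("  index range:", paste(format(range(x$index), digits = 3),
                              collapse = " .. "), "\n")
  invisible(x)
}

#' @method summary diff_index
#' @export
summary.diff_index <- function(object, labels = NULL, ...) {
  if (is.null(labels)) {
    return(summary(object$index))
  }
  potency_test(object, labels, ...)
}

#' Test each TF's cell-fate-conversion potency
#'
#' For every TF with enough single-iTF cells, compares that population's
#' differentiation indexes against the control cells' with a one-sided
#' Mann-Whitney U test (alternative: TF indexes are greater), then adjusts
#' p-values across tested TFs. A TF is called potent when its adjusted
#' p-value falls below `alpha`.
#'
#' @param index a `diff_index` object or a named per-cell index vector.
#' @param labels cell assignment data.frame from [classify_cells] (columns
#'   `cell_barcode`, `label`, `tf_name`).
#' @param alpha significance level on the adjusted p-value (default 0.01).
#' @param adjust multiple-testing method for [stats::p.adjust] (default
#'   `"BH"`).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param min_cells minimum single-iTF cells for a TF to be tested
#'   (default 3; smaller groups are reported untested).
#' @return data.frame per TF: `tf_name`, `n_cells`, `median_index`, `U`,
#'   `p`, `p_adj`, `tested`, `potent`.
#' @export
potency_test <- function(index, labels, alpha = 0.01, adjust = "BH",
                         alternative = c("greater", "two.sided"),
                         min_cells = 3L) {
  alternative <- match.arg(alternative)
  idx <- if (inherits(index, "diff_index")) index$index else index
  ctrl_cells <- if (inherits(index, "diff_index")) index$control_cells else
    labels$cell_barcode[labels$label == "control"]
  ctrl_idx <- idx[intersect(ctrl_cells, names(idx))]
  if (length(ctrl_idx) < 1) stop("no control cells with an index",
                                 call. = FALSE)
  singles <- labels[labels$label == "single" & !is.na(labels$tf_name), ,
                    drop = FALSE]
  tfs <- sort(unique(singles$tf_name))
  out <- data.frame(tf_name = tfs, n_cells = NA_integer_,
                    median_index = NA_real_, U = NA_real_, p = NA_real_,
                    p_adj = NA_real_, tested = FALSE, potent = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(tfs)) {
    cells <- singles$cell_barcode[singles$tf_name == tfs[i]]
    v <- idx[intersect(cells, names(idx))]
    out$n_cells[i] <- length(v)
    out$median_index[i] <- median(v)
    if (length(v) >= min_cells) {
      wt <- suppressWarnings(
        wilcox.test(v, ctrl_idx, alternative = alternative))
      out$U[i] <- unname(wt$statistic)
      out$p[i] <- wt$p.value
      out$tested[i] <- TRUE
    }
  }
  out$p_adj[out$tested] <- p.adjust(out$p[out$tested], method = adjust)
  out$potent <- out$tested & !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Percentile ranks of per-TF medians
#'
#' Places each TF's median index among all TFs on a 0-100 scale so indexes
#' computed on gene sets with different ranges can be compared. The rank is
#' `100 * (#smaller + 0.5 * #ties-excluding-self) / (n - 1)`: the largest
#' value maps to 100, the smallest to 0, and full ties map to 50.
#'
#' @param medians named numeric vector of per-TF medians (length >= 2).
#' @return named numeric vector of ranks in \[0, 100\].
#' @export
percentile_ranks <- function(medians) {
  n <- length(medians)
  if (n < 2) stop("need at least 2 values to rank", call. = FALSE)
  vapply(seq_len(n), function(i) {
    smaller <- sum(medians < medians[i])
    ties <- sum(medians == medians[i]) - 1L
    100 * (smaller + 0.5 * ties) / (n - 1)
  }, numeric(1)) -> r
  names(r) <- names(medians)
  r
}
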