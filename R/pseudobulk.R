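#' Pseudobulk profiles per iTF group
#'
#' Averages normalized expression per gene over each single-iTF group and
#' over the control cells. Groups with fewer than 3 cells are flagged
#' (`low_n`) so downstream per-group analyses can exclude them.
#'
#' @param norm gene x cell normalized matrix (log-normalized values are the
#'   intended input).
#' @param labels cell assignments from [classify_cells].
#' @return list of class `pseudobulk`: `means` (gene x group matrix),
#'   `n_cells` (named counts), `low_n` (named logical).
#' @export
pseudobulk_means <- function(norm, labels) {
  singles <- labels[labels$label == "single" & !is.na(labels$tf_name), ,
                    drop = FALSE]
  groups <- split(singles$cell_barcode, singles$tf_name)
  groups <- c(groups,
              list(control = labels$cell_barcode[labels$label == "control"]))
  groups <- lapply(groups, intersect, colnames(norm))
  groups <- groups[vapply(groups, length, integer(1)) >= 1L]
  if (length(groups) == 0) stop("no group has any cells", call. = FALSE)
  means <- vapply(groups, function(cells) {
    rowMeans(norm[, cells, drop = FALSE])
  }, numeric(nrow(norm)))
  n_cells <- vapply(groups, length, integer(1))
  structure(list(means = means, n_cells = n_cells, low_n = n_cells < 3L),
            class = "pseudobulk")
}

#' @method print pseudobulk
#' @export
print.pseudobulk <- function(x, ...) {
  cat("Pseudobulk:", nrow(x$means), "genes x", ncol(x$means), "groups;",
      sum(x$low_n), "group(s) with < 3 cells\n")
  invisible(x)
}

#' Marker-panel report relative to the control group
#'
#' Reports each group's expression of a marker panel relative to the control
#' group: by default the ratio of de-logged group means (so the control
#' column is exactly 1); `mode = "log_diff"` reports the difference of
#' log-space means instead (control column 0).
#'
#' @param pb a [pseudobulk_means] result.
#' @param panel character vector of marker gene names (e.g. pluripotency
#'   markers Pou5f1, Sox2, Nanog, Klf4).
#' @param reference_group reference column name (default `"control"`).
#' @param mode `"ratio"` (default) or `"log_diff"`.
#' @return list with `relative` (marker x group matrix) and `missing`
#'   (panel genes absent from the matrix).
#' @export
marker_report <- function(pb, panel, reference_group = "control",
                          mode = c("ratio", "log_diff")) {
  mode <- match.arg(mode)
  stopifnot(reference_group %in% colnames(pb$means))
  found <- intersect(panel, rownames(pb$means))
  missing <- setdiff(panel, found)
  if (length(missing))
    warning("MissingGene: ", paste(missing, collapse = ", "),
            call. = FALSE)
  if (length(found) == 0) stop("no panel gene present", call. = FALSE)
  m <- pb$means[found, , drop = FALSE]
  rel <- if (mode == "ratio") {
    e <- expm1(m)
    sweep(e, 1L, e[, reference_group], `/`)
  } else {
    sweep(m, 1L, m[, reference_group], `-`)
  }
  list(relative = rel, missing = missing, mode = mode)
}

#' Moving-window average of an ordered series
#'
#' `out[i]` is the mean of `values[i .. i + window - 1]` for every full
#' window, advancing `step` positions between windows. Used to smooth, e.g.,
#' binding peak scores over genes ordered by relative expression.
#'
#' @param values numeric series, already ordered.
#' @param window window size (default 100).
#' @param step stride between windows (default 1).
#' @return numeric vector of length `floor((n - window) / step) + 1`.
#' @export
moving_window_average <- function(values, window = 100L, step = 1L) {
  n <- length(values)
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(window >= 1L, step >= 1L)
  if (n < window)
    stop("SeriesTooShort: length ", n, " < window ", window, call. = FALSE)
  cs <- cumsum(c(0, values))
  starts <- seq.int(1L, n - window + 1L, by = step)
  (cs[starts + window] - cs[starts]) / window
}

#' Permute peak scores across genes
#'
#' Produces the randomized comparison series for expression-rank versus
#' binding-score plots: the scores are permuted over genes, breaking any
#' association with the expression ordering while preserving the score
#' distribution.
#'
#' @param scores numeric vector of per-gene scores.
#' @param seed optional integer seed for reproducibility.
#' @return permuted numeric vector of the same length.
#' @export
permute_scores <- function(scores, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores[sample.int(length(scores))]
}
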