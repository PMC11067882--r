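# Random DNA sequences: n strings of length len.
.random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Poisson draws truncated to >= 1 (zeros redrawn).
.rpois_pos <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- rpois(sum(x == 0), lambda)
  x
}

#' Simulate tag-bearing reads with ambient contamination
#'
#' Emulates the read-level evidence of a pooled iTF screen: every cell
#' carries exactly one true induced TF whose transcript count is Poisson
#' (truncated to at least one molecule); with probability
#' `contamination_prob` the cell additionally picks up 1-2 ambient molecules
#' of one random other TF (the mechanism behind spurious multi-iTF cells).
#' Each molecule (UMI) emits `reads_per_umi` reads containing the TF's
#' forward or reverse junction tag at a random offset, on a random strand,
#' with optional substitution noise. Deterministic given `seed`.
#'
#' @param tags tag table from [build_tag_table].
#' @param n_cells number of cells (default 1000).
#' @param umi_mean Poisson mean of true molecules per cell (default 8).
#' @param contamination_prob probability a cell gains an ambient TF
#'   (default 0.5).
#' @param contamination_umis possible ambient molecule counts, sampled
#'   uniformly (default `1:2`).
#' @param reads_per_umi reads emitted per molecule (default 3).
#' @param error_rate per-base substitution probability (default 0).
#' @param read_length read length in nt (default 90).
#' @param seed integer seed; set for reproducible output.
#' @return list with `reads` (data.frame: `read_id`, `cell_barcode`, `umi`,
#'   `sequence`, `aligner_gene`), `truth_reads` (per-read ground truth with
#'   `is_contaminant`), `truth_cells` (per-cell true TF and contamination
#'   status), and `params`.
#' @export
simulate_tag_reads <- function(tags, n_cells = 1000L, umi_mean = 8,
                               contamination_prob = 0.5,
                               contamination_umis = 1:2,
                               reads_per_umi = 3L, error_rate = 0,
                               read_length = 90L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tf <- tags$tf_name
  stopifnot(length(tf) >= 2, read_length >= max(nchar(tags$forward_tag),
                                                nchar(tags$reverse_tag)))
  barcodes <- .random_dna(n_cells, 16L)
  true_tf <- sample(tf, n_cells, replace = TRUE)
  n_true <- .rpois_pos(n_cells, umi_mean)
  contam <- runif(n_cells) < contamination_prob
  other <- vapply(true_tf, function(t) sample(setdiff(tf, t), 1L),
                  character(1), USE.NAMES = FALSE)
  n_contam <- integer(n_cells)
  n_contam[contam] <- contamination_umis[
    sample.int(length(contamination_umis), sum(contam), replace = TRUE)]

  # one row per molecule
  umi_tbl <- data.frame(
    cell_barcode = c(rep(barcodes, n_true), rep(barcodes, n_contam)),
    tf_name = c(rep(true_tf, n_true), rep(other, n_contam)),
    is_contaminant = c(rep(FALSE, sum(n_true)), rep(TRUE, sum(n_contam))),
    stringsAsFactors = FALSE)
  umi_tbl$umi <- .random_dna(nrow(umi_tbl), 12L)

  # one row per read
  rid <- rep(seq_len(nrow(umi_tbl)), each = reads_per_umi)
  reads <- umi_tbl[rid, , drop = FALSE]
  n_reads <- nrow(reads)
  reads$read_id <- sprintf("read%07d", seq_len(n_reads))

  ti <- match(reads$tf_name, tags$tf_name)
  use_fwd <- runif(n_reads) < 0.5
  tagseq <- ifelse(use_fwd, tags$forward_tag[ti], tags$reverse_tag[ti])
  flip <- runif(n_reads) < 0.5
  tagseq[flip] <- revcomp(tagseq[flip])
  tlen <- nchar(tagseq)
  offset <- floor(runif(n_reads) * (read_length - tlen + 1))
  bg <- .random_dna(n_reads, read_length)
  seqs <- paste0(substr(bg, 1L, offset),
                 tagseq,
                 substr(bg, offset + tlen + 1L, read_length))
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_length, n_err[i])
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      ch[pos] <- sample(c("A", "C", "G", "T"), n_err[i], replace = TRUE)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  out_reads <- data.frame(read_id = reads$read_id,
                          cell_barcode = reads$cell_barcode,
                          umi = reads$umi, sequence = seqs,
                          aligner_gene = NA_character_,
                          stringsAsFactors = FALSE)
  truth_reads <- data.frame(read_id = reads$read_id,
                            cell_barcode = reads$cell_barcode,
                            umi = reads$umi, tf_name = reads$tf_name,
                            is_contaminant = reads$is_contaminant,
                            stringsAsFactors = FALSE)
  truth_cells <- data.frame(cell_barcode = barcodes, true_tf = true_tf,
                            n_true_umis = n_true,
                            contaminant_tf = ifelse(contam, other,
                                                    NA_character_),
                            n_contaminant_umis = as.integer(n_contam),
                            stringsAsFactors = FALSE)
  list(reads = out_reads, truth_reads = truth_reads,
       truth_cells = truth_cells,
       params = list(n_cells = n_cells, umi_mean = umi_mean,
                     contamination_prob = contamination_prob,
                     contamination_umis = contamination_umis,
                     reads_per_umi = reads_per_umi,
                     error_rate = error_rate, read_length = read_length,
                     seed = seed))
}

#' Default population layout for a simulated expression cohort
#'
#' @param n_potent,n_null numbers of perturbed populations with and without a
#'   planted transcriptome shift.
#' @param n_cells cells per population.
#' @param shifted_genes genes shifted per potent population.
#' @param shift log-scale mean shift applied to those genes.
#' @return data.frame of population specs for [simulate_expression_cohort].
#' @export
cohort_populations <- function(n_potent = 10L, n_null = 10L, n_cells = 100L,
                               shifted_genes = 50L, shift = 2.0) {
  data.frame(
    name = sprintf("TF%02d", seq_len(n_potent + n_null)),
    n_cells = n_cells,
    shifted_genes = c(rep(shifted_genes, n_potent), rep(0L, n_null)),
    shift = c(rep(shift, n_potent), rep(0, n_null)),
    is_null = c(rep(FALSE, n_potent), rep(TRUE, n_null)),
    stringsAsFactors = FALSE)
}

#' Simulate an expression cohort with planted potent populations
#'
#' Draws a control population and a set of perturbed populations from a
#' negative binomial count model. Baseline per-gene means are log-normal;
#' potent populations multiply the means of `shifted_genes` randomly chosen
#' genes (disjoint from the iTF gene list) by `exp(shift)`; null populations
#' are drawn from the unmodified baseline. One gene is named after each
#' population's TF so the iTF-gene exclusion path is exercised downstream.
#' Deterministic given `seed`.
#'
#' @param n_genes total genes (default 2000).
#' @param n_control control cells (default 2000).
#' @param populations data.frame of specs (see [cohort_populations]).
#' @param dispersion negative binomial dispersion (default 0.3; NB size =
#'   1/dispersion).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   means (defaults 0 and 1).
#' @param seed integer seed.
#' @return list with `counts` (gene x cell integer matrix), `labels`
#'   (data.frame `cell_barcode`, `label`, `tf_name`), `itf_genes`,
#'   `truth` (per population: shifted genes, is_potent), `params`.
#' @export
simulate_expression_cohort <- function(n_genes = 2000L, n_control = 2000L,
                                       populations = cohort_populations(),
                                       dispersion = 0.3,
                                       base_meanlog = 0, base_sdlog = 1,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(populations) >= 1, n_genes > nrow(populations))
  itf_genes <- populations$name
  gene_names <- c(itf_genes,
                  sprintf("gene%05d", seq_len(n_genes - length(itf_genes))))
  base_mu <- exp(rnorm(n_genes, base_meanlog, base_sdlog))
  names(base_mu) <- gene_names
  size <- 1 / dispersion

  draw <- function(mu, n) {
    matrix(rnbinom(n_genes * n, mu = rep(mu, n), size = size), n_genes, n)
  }
  ctrl <- draw(base_mu, n_control)
  blocks <- list(ctrl)
  lab <- data.frame(cell_barcode = sprintf("ctrl%05d", seq_len(n_control)),
                    label = "control", tf_name = NA_character_,
                    stringsAsFactors = FALSE)
  truth <- vector("list", nrow(populations))
  non_itf <- setdiff(gene_names, itf_genes)
  for (i in seq_len(nrow(populations))) {
    p <- populations[i, ]
    mu <- base_mu
    shifted <- character(0)
    if (p$shifted_genes > 0 && p$shift != 0) {
      shifted <- sample(non_itf, p$shifted_genes)
      mu[shifted] <- mu[shifted] * exp(p$shift)
    }
    blocks[[i + 1L]] <- draw(mu, p$n_cells)
    lab <- rbind(lab, data.frame(
      cell_barcode = sprintf("%s_cell%04d", p$name, seq_len(p$n_cells)),
      label = "single", tf_name = p$name, stringsAsFactors = FALSE))
    truth[[i]] <- list(name = p$name, shifted_genes = shifted,
                       is_potent = !p$is_null && p$shift != 0 &&
                         p$shifted_genes > 0)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- gene_names
  colnames(counts) <- lab$cell_barcode
  list(counts = counts, labels = lab, itf_genes = itf_genes,
       truth = truth,
       params = list(n_genes = n_genes, n_control = n_control,
                     dispersion = dispersion, base_meanlog = base_meanlog,
                     base_sdlog = base_sdlog, seed = seed))
}
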