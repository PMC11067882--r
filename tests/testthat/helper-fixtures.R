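# Shared fixture builders. Everything is generated in code under fixed seeds.

BASES <- c("A", "C", "G", "T")

random_dna_str <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# A random ORF with proper start/stop codons.
random_orf <- function(inner_len = 60) {
  paste0("ATG", random_dna_str(inner_len), "TAA")
}

make_orfs <- function(n, inner_len = 60, prefix = "Tf") {
  stats::setNames(replicate(n, random_orf(inner_len)), sprintf("%s%02d", prefix, seq_len(n)))
}

VEC_UP <- "GGACTTCCAT"    # vector context upstream of the start codon
VEC_DOWN <- "GCTAGCGTTCG" # vector context downstream of the stop codon

make_tags <- function(n = 5, seed = 42) {
  withr::with_seed(seed, {
    orfs <- make_orfs(n)
    build_tag_table(orfs, VEC_UP, VEC_DOWN)
  })
}

# Brute-force sliding-window Hamming scan: the independent oracle for
# scan_reads. Searches each pattern (tag and its reverse complement) at every
# offset of every read; O(reads x offsets x patterns).
oracle_scan <- function(reads, tags, max_mismatches = 0L) {
  pats <- rbind(
    data.frame(tf_name = tags$tf_name, orientation = "forward",
               tag = tags$forward_tag, stringsAsFactors = FALSE),
    data.frame(tf_name = tags$tf_name, orientation = "reverse",
               tag = tags$reverse_tag, stringsAsFactors = FALSE))
  keep <- !is.na(reads$cell_barcode) & reads$cell_barcode != "" &
    !is.na(reads$umi) & reads$umi != ""
  reads <- reads[keep, , drop = FALSE]
  rl <- nchar(reads$sequence)
  stopifnot(length(unique(rl)) <= 1)  # oracle assumes equal-length reads
  if (nrow(reads) == 0 || length(rl) == 0) return(NULL)
  chm <- do.call(rbind, strsplit(reads$sequence, "", fixed = TRUE))
  out <- list(); k <- 0L
  for (i in seq_len(nrow(pats))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pats$tag[i] else revcomp(pats$tag[i])
      pv <- strsplit(pat, "", fixed = TRUE)[[1]]
      w <- length(pv)
      if (w > rl[1]) next
      for (off in 0:(rl[1] - w)) {
        mm <- rowSums(chm[, (off + 1):(off + w), drop = FALSE] !=
                        matrix(pv, nrow(chm), w, byrow = TRUE))
        hit <- which(mm <= max_mismatches)
        if (length(hit)) {
          k <- k + 1L
          out[[k]] <- data.frame(read_id = reads$read_id[hit],
                                 tf_name = pats$tf_name[i],
                                 orientation = pats$orientation[i],
                                 strand = strand, position = off,
                                 mismatches = as.integer(mm[hit]),
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0) return(NULL)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$read_id, res$tf_name, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Long-form UMI count table from a simple list spec:
# list(A = c(tfA = 5), B = c(tfA = 8, tfB = 2), ...)
umi_table_from_list <- function(spec) {
  do.call(rbind, lapply(names(spec), function(cell) {
    v <- spec[[cell]]
    data.frame(cell_barcode = cell, tf_name = names(v),
               n_umis = as.integer(v), stringsAsFactors = FALSE)
  }))
}

# Exhaustive one-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled ranks to the first group. P(U >= u_obs) under the null.
oracle_mw_greater <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
  mean(us >= u_obs - 1e-12)
}
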