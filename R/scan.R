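#' Scan reads for junction tags
#'
#' Reports every occurrence of any tag (forward or reverse, searched on both
#' strands of the read) as a substring of the read sequence, allowing up to
#' `max_mismatches` substitutions and no indels. Reads missing a cell barcode
#' or UMI are dropped before scanning; drop counts are attached as the
#' `"scan_log"` attribute.
#'
#' @param reads data.frame with columns `read_id`, `cell_barcode`, `umi`,
#'   `sequence` (and optionally `aligner_gene`).
#' @param tags tag table from [build_tag_table] or [read_tag_table].
#' @param max_mismatches maximum number of substitutions tolerated (default 0,
#'   exact matching).
#' @return data.frame of hits with columns `read_id`, `tf_name`,
#'   `orientation` (`"forward"`/`"reverse"`: which tag matched), `strand`
#'   (`"+"` if the tag matched the read as given, `"-"` if its reverse
#'   complement did), `position` (0-based offset in the read), `mismatches`.
#' @export
scan_reads <- function(reads, tags, max_mismatches = 0L) {
  stopifnot(is.data.frame(reads), nrow(tags) > 0)
  n_in <- nrow(reads)
  ok <- !is.na(reads$cell_barcode) & reads$cell_barcode != "" &
    !is.na(reads$umi) & reads$umi != ""
  n_dropped <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  if (nrow(reads) == 0) {
    hits <- data.frame(read_id = character(0), tf_name = character(0),
                       orientation = character(0), strand = character(0),
                       position = integer(0), mismatches = integer(0))
    attr(hits, "scan_log") <- list(n_reads_in = n_in,
                                   n_dropped_no_barcode_or_umi = n_dropped,
                                   n_reads_scanned = 0L)
    return(hits)
  }

  widths <- nchar(reads$sequence)

  pats <- data.frame(
    tf_name = rep(tags$tf_name, 2L),
    orientation = rep(c("forward", "reverse"), each = nrow(tags)),
    tag = c(tags$forward_tag, tags$reverse_tag),
    stringsAsFactors = FALSE)

  # concatenate all reads into one subject separated by runs of N (N never
  # matches an ACGT tag base), so each tag needs a single C-level scan; match
  # positions are then mapped back to reads and boundary-crossing windows
  # discarded
  sep_w <- max(nchar(pats$tag)) + max_mismatches
  big <- Biostrings::DNAString(
    paste(reads$sequence, collapse = strrep("N", sep_w)))
  starts <- cumsum(c(1L, widths[-length(widths)] + sep_w))

  res <- vector("list", 4L * nrow(pats))
  k <- 0L
  for (i in seq_len(nrow(pats))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pats$tag[i] else revcomp(pats$tag[i])
      w <- nchar(pat)
      m <- Biostrings::matchPattern(pat, big,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      st <- BiocGenerics::start(m)
      if (length(st) == 0) next
      st <- st[st >= 1L & st + w - 1L <= length(big)]
      if (length(st) == 0) next
      ri <- findInterval(st, starts)
      # keep matches fully inside a read (not spanning a separator)
      off <- st - starts[ri]
      inb <- off >= 0L & off + w <= widths[ri]
      if (!any(inb)) next
      ri <- ri[inb]; off <- off[inb]
      mm <- .count_mismatches(substr(reads$sequence[ri], off + 1L, off + w),
                              pat)
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      k <- k + 1L
      res[[k]] <- data.frame(read_id = reads$read_id[ri[keep]],
                             tf_name = pats$tf_name[i],
                             orientation = pats$orientation[i],
                             strand = strand,
                             position = as.integer(off[keep]),
                             mismatches = mm[keep],
                             stringsAsFactors = FALSE)
    }
  }
  hits <- if (k > 0) do.call(rbind, res[seq_len(k)]) else
    data.frame(read_id = character(0), tf_name = character(0),
               orientation = character(0), strand = character(0),
               position = integer(0), mismatches = integer(0))
  hits <- unique(hits)
  hits <- hits[order(hits$read_id, hits$tf_name, hits$position), ,
               drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "scan_log") <- list(n_reads_in = n_in,
                                 n_dropped_no_barcode_or_umi = n_dropped,
                                 n_reads_scanned = nrow(reads))
  hits
}

# Hamming distance between equal-length strings x (vector) and pattern pat.
.count_mismatches <- function(x, pat) {
  if (length(x) == 0) return(integer(0))
  pm <- charToRaw(pat)
  vapply(x, function(s) sum(charToRaw(s) != pm), integer(1), USE.NAMES = FALSE)
}

#' Aggregate tag hits to transcript (UMI) level
#'
#' Groups tag-bearing reads by (cell barcode, UMI) and assigns each transcript
#' the TF supported by the most reads in its group. A tie between TFs excludes
#' the transcript (reason `"tf_tie"`).
#'
#' @param hits hit table from [scan_reads].
#' @param reads the read table the hits refer to.
#' @return data.frame with one row per (cell_barcode, umi) having at least one
#'   tag hit: `cell_barcode`, `umi`, `tf_name`, `n_reads_supporting`,
#'   `n_reads_total`, `excluded`, `exclusion_reason`.
#' @export
aggregate_umis <- function(hits, reads) {
  rd <- data.table::as.data.table(
    reads[, c("read_id", "cell_barcode", "umi")])
  group_tot <- rd[, list(n_reads_total = .N), by = c("cell_barcode", "umi")]

  if (nrow(hits) == 0) {
    out <- data.frame(cell_barcode = character(0), umi = character(0),
                      tf_name = character(0), n_reads_supporting = integer(0),
                      n_reads_total = integer(0), excluded = logical(0),
                      exclusion_reason = character(0))
    return(out)
  }
  ht <- data.table::as.data.table(unique(hits[, c("read_id", "tf_name")]))
  ht <- merge(ht, rd, by = "read_id")
  tal <- ht[, list(n = data.table::uniqueN(read_id)),
            by = c("cell_barcode", "umi", "tf_name")]
  data.table::setorderv(tal, c("cell_barcode", "umi", "n", "tf_name"),
                        order = c(1L, 1L, -1L, 1L))
  win <- tal[, list(tf_name = tf_name[1L],
                    n_reads_supporting = n[1L],
                    tie = .N > 1L && n[2L] == n[1L]),
             by = c("cell_barcode", "umi")]
  out <- merge(win, group_tot, by = c("cell_barcode", "umi"))
  out[, `:=`(excluded = tie,
             exclusion_reason = data.table::fifelse(tie, "tf_tie",
                                                    NA_character_))]
  out[tie == TRUE, tf_name := NA_character_]
  out[, tie := NULL]
  data.table::setDF(out)
  out <- out[order(out$cell_barcode, out$umi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude transcripts that conflict with an external aligner's annotation
#'
#' For each UMI assignment, computes the fraction of its reads whose
#' aligner-derived gene label is present, not `"NA"`, and different from the
#' tag-derived TF. If that fraction exceeds one half the transcript is
#' excluded (reason `"aligner_conflict"`). Transcripts whose reads are all
#' unannotated or labelled `"NA"` are retained.
#'
#' @param assignments UMI assignment table from [aggregate_umis].
#' @param reads the read table, with an `aligner_gene` column (values may be
#'   `NA` or the string `"NA"` for unannotated reads).
#' @return the assignment table with conflicting transcripts marked excluded.
#' @export
resolve_gene_conflicts <- function(assignments, reads) {
  if (!"aligner_gene" %in% names(reads) || nrow(assignments) == 0)
    return(assignments)
  rd <- data.table::as.data.table(
    reads[, c("cell_barcode", "umi", "aligner_gene")])
  idx <- which(!assignments$excluded)
  if (length(idx) == 0) return(assignments)
  asn <- data.table::as.data.table(
    assignments[idx, c("cell_barcode", "umi", "tf_name")])
  mg <- merge(rd, asn, by = c("cell_barcode", "umi"))
  mg[, conflict := !is.na(aligner_gene) & aligner_gene != "NA" &
       aligner_gene != tf_name]
  fr <- mg[, list(f = mean(conflict)), by = c("cell_barcode", "umi")]
  bad <- fr[f > 0.5]
  if (nrow(bad) > 0) {
    key <- paste(assignments$cell_barcode, assignments$umi, sep = "\r")
    hit <- key %in% paste(bad$cell_barcode, bad$umi, sep = "\r") &
      !assignments$excluded
    assignments$excluded[hit] <- TRUE
    assignments$exclusion_reason[hit] <- "aligner_conflict"
  }
  assignments
}

#' UMI count table: molecules per (cell, TF)
#'
#' Counts non-excluded UMI assignments per (cell barcode, TF) pair.
#'
#' @param assignments assignment table from [aggregate_umis] (after
#'   [resolve_gene_conflicts] if aligner annotations are available).
#' @return data.frame with columns `cell_barcode`, `tf_name`, `n_umis`.
#' @export
umi_count_table <- function(assignments) {
  keep <- assignments[!assignments$excluded, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(cell_barcode = character(0), tf_name = character(0),
                      n_umis = integer(0)))
  dt <- data.table::as.data.table(keep[, c("cell_barcode", "tf_name")])
  out <- dt[, list(n_umis = .N), by = c("cell_barcode", "tf_name")]
  data.table::setorderv(out, c("cell_barcode", "tf_name"))
  data.table::setDF(out)
  out
}

#' Read a tabular read file
#'
#' Expects columns `read_id`, `cell_barcode`, `umi`, `sequence`, and
#' optionally `aligner_gene`.
#'
#' @param path TSV file path.
#' @return data.frame of reads.
#' @export
read_reads_tsv <- function(path) {
  rd <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("read_id", "cell_barcode", "umi", "sequence")
  miss <- setdiff(need, names(rd))
  if (length(miss))
    stop("read table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rd
}

#' Parse a 10x-style paired FASTQ into a read table
#'
#' Mate 1 carries the cell barcode and UMI (default layout: 16-nt barcode
#' followed by a 12-nt UMI); mate 2 is the cDNA sequence that is scanned for
#' tags.
#'
#' @param r1,r2 FASTQ paths for mate 1 (barcode+UMI) and mate 2 (cDNA).
#' @param barcode_len,umi_len barcode/UMI layout of mate 1.
#' @return data.frame of reads as accepted by [scan_reads].
#' @export
read_fastq_pair <- function(r1, r2, barcode_len = 16L, umi_len = 12L) {
  q1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  q2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(q1) != length(q2))
    stop("FASTQ mates have different read counts", call. = FALSE)
  s1 <- as.character(q1)
  bc <- substr(s1, 1L, barcode_len)
  um <- substr(s1, barcode_len + 1L, barcode_len + umi_len)
  short <- nchar(s1) < barcode_len + umi_len
  bc[short] <- ""
  um[short] <- ""
  data.frame(read_id = sub("\\s.*$", "", names(q1)),
             cell_barcode = bc, umi = um,
             sequence = as.character(q2), stringsAsFactors = FALSE)
}
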