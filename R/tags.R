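#' Reverse complement of DNA strings
#'
#' @param x character vector over the ACGT alphabet.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.check_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("InvalidAlphabet: ", what, " contains characters other than A/C/G/T (",
         paste(head(which(bad), 3), collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' Build the forward junction tag for one ORF
#'
#' The forward tag spans the vector-ORF junction at the start codon: the last
#' `vector_len` nt transcribed from the vector immediately upstream of the
#' insert, followed by the first `core_len` nt of the coding sequence. With
#' the defaults (7 + 21) the tag is 28 nt, unique to the ectopic transcript.
#'
#' @param cds coding sequence (ACGT string), including start and stop codons.
#' @param upstream vector sequence transcribed immediately 5' of the insert.
#' @param core_len number of ORF nucleotides in the tag (default 21).
#' @param vector_len number of vector nucleotides in the tag (default 7).
#' @return the tag as a single string of length `vector_len + core_len`.
#' @export
build_forward_tag <- function(cds, upstream, core_len = 21L, vector_len = 7L) {
  .check_acgt(cds, "cds"); .check_acgt(upstream, "upstream")
  if (nchar(cds) < core_len)
    stop("CdsTooShort: cds has ", nchar(cds), " nt, need >= ", core_len,
         call. = FALSE)
  if (nchar(upstream) < vector_len)
    stop("VectorContextTooShort: upstream has ", nchar(upstream),
         " nt, need >= ", vector_len, call. = FALSE)
  if (!startsWith(cds, "ATG"))
    warning("MissingStartCodon: cds does not begin with ATG", call. = FALSE)
  up <- if (vector_len > 0)
    substr(upstream, nchar(upstream) - vector_len + 1L, nchar(upstream))
  else ""
  paste0(up, substr(cds, 1L, core_len))
}

#' Build the reverse junction tag for one ORF
#'
#' The reverse tag spans the stop-codon junction: the last `core_len` nt of
#' the coding sequence (including the stop codon) concatenated with the first
#' `vector_len` nt of the vector downstream of the insert, reverse
#' complemented so it matches reads from the 3' end of the transcript.
#'
#' @inheritParams build_forward_tag
#' @param downstream vector sequence immediately 3' of the stop codon.
#' @return the tag as a single string of length `vector_len + core_len`.
#' @export
build_reverse_tag <- function(cds, downstream, core_len = 21L, vector_len = 7L) {
  .check_acgt(cds, "cds"); .check_acgt(downstream, "downstream")
  if (nchar(cds) < core_len)
    stop("CdsTooShort: cds has ", nchar(cds), " nt, need >= ", core_len,
         call. = FALSE)
  if (nchar(downstream) < vector_len)
    stop("VectorContextTooShort: downstream has ", nchar(downstream),
         " nt, need >= ", vector_len, call. = FALSE)
  tail3 <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!tail3 %in% c("TAA", "TAG", "TGA"))
    warning("MissingStopCodon: cds does not end with TAA/TAG/TGA",
            call. = FALSE)
  core <- substr(cds, nchar(cds) - core_len + 1L, nchar(cds))
  down <- if (vector_len > 0) substr(downstream, 1L, vector_len) else ""
  revcomp(paste0(core, down))
}

# TRUE if `tag` occurs as an exact substring of any sequence in `genome`
# (either strand). `genome` is a character vector or DNAStringSet.
.tag_in_genome <- function(tag, genome) {
  if (is.null(genome) || length(genome) == 0) return(FALSE)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(as.character(genome))
  hits <- sum(Biostrings::vcountPattern(tag, genome)) +
    sum(Biostrings::vcountPattern(revcomp(tag), genome))
  hits > 0
}

#' Extend a junction tag until it is unique
#'
#' A candidate tag that occurs in the reference genome (either strand) or is
#' identical to another factor's tag cannot identify the ectopic transcript.
#' The tag is lengthened on the ORF side one nucleotide at a time, re-checking
#' after each extension, until it is unique or `max_len` is reached.
#'
#' @param cds,core_len,vector_len as in [build_forward_tag].
#' @param context the vector context on the relevant side (`upstream` for a
#'   forward tag, `downstream` for a reverse tag).
#' @param which `"forward"` or `"reverse"`.
#' @param genome optional reference sequences (character or `DNAStringSet`).
#' @param other_tags character vector of tags already claimed by other ORFs.
#' @param max_len maximum allowed tag length (default 50).
#' @return list with `tag`, `core_len`, `extended`.
#' @export
extend_tag_for_uniqueness <- function(cds, context,
                                      which = c("forward", "reverse"),
                                      genome = NULL, other_tags = character(0),
                                      core_len = 21L, vector_len = 7L,
                                      max_len = 50L) {
  which <- match.arg(which)
  make <- function(k) {
    if (nchar(cds) < k) return(NA_character_)
    if (which == "forward") {
      suppressWarnings(build_forward_tag(cds, context, k, vector_len))
    } else {
      suppressWarnings(build_reverse_tag(cds, context, k, vector_len))
    }
  }
  k <- as.integer(core_len)
  tag <- make(k)
  collides <- function(t) .tag_in_genome(t, genome) || t %in% other_tags
  extended <- FALSE
  while (!is.na(tag) && collides(tag) && (k + vector_len) < max_len) {
    k <- k + 1L
    tag <- make(k)
    extended <- TRUE
  }
  if (is.na(tag) || collides(tag))
    stop("UniquenessUnreachable: no unique ", which, " tag within ",
         max_len, " nt", call. = FALSE)
  list(tag = tag, core_len = k, extended = extended)
}

#' Build the junction-tag table for a set of ORFs
#'
#' Constructs forward and reverse tags for every ORF, then resolves
#' collisions: any tag found in the supplied genome (either strand) or
#' identical to another tag is extended on the ORF side until unique.
#'
#' @param orfs named character vector of coding sequences (names = TF names),
#'   or a data.frame with columns `name` and `cds`.
#' @param upstream,downstream vector context sequences flanking the insert.
#' @param genome optional reference sequences used for the uniqueness check.
#' @param core_len,vector_len,max_len tag geometry; see [build_forward_tag].
#' @return data.frame with columns `tf_name`, `forward_tag`, `reverse_tag`,
#'   `forward_len`, `reverse_len`, `extended`.
#' @export
build_tag_table <- function(orfs, upstream, downstream, genome = NULL,
                            core_len = 21L, vector_len = 7L, max_len = 50L) {
  if (is.data.frame(orfs)) orfs <- stats::setNames(orfs$cds, orfs$name)
  nms <- names(orfs)
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    stop("orfs must be named (TF names)", call. = FALSE)
  if (anyDuplicated(nms))
    stop("DuplicateName: ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)

  n <- length(orfs)
  fwd <- character(n); rev_ <- character(n); ext <- logical(n)
  for (i in seq_len(n)) {
    fwd[i] <- build_forward_tag(orfs[[i]], upstream, core_len, vector_len)
    rev_[i] <- build_reverse_tag(orfs[[i]], downstream, core_len, vector_len)
  }
  # collision resolution: each tag must avoid the genome and all other tags
  for (i in seq_len(n)) {
    others <- c(fwd[-i], rev_[-i], rev_[i])
    rf <- extend_tag_for_uniqueness(orfs[[i]], upstream, "forward", genome,
                                    others, core_len, vector_len, max_len)
    fwd[i] <- rf$tag
    others <- c(fwd[-i], rev_[-i], fwd[i])
    rr <- extend_tag_for_uniqueness(orfs[[i]], downstream, "reverse", genome,
                                    others, core_len, vector_len, max_len)
    rev_[i] <- rr$tag
    ext[i] <- rf$extended || rr$extended
  }
  out <- data.frame(tf_name = nms, forward_tag = fwd, reverse_tag = rev_,
                    forward_len = nchar(fwd), reverse_len = nchar(rev_),
                    extended = ext, stringsAsFactors = FALSE)
  if (anyDuplicated(c(out$forward_tag, out$reverse_tag)))
    stop("UniquenessUnreachable: duplicate tags remain after extension",
         call. = FALSE)
  class(out) <- c("tag_table", "data.frame")
  out
}

#' @method print tag_table
#' @export
print.tag_table <- function(x, ...) {
  cat("Junction-tag table:", nrow(x), "TFs;",
      sum(x$extended), "tag(s) extended beyond the default length\n")
  NextMethod()
}

#' Read ORF coding sequences from a FASTA file
#'
#' @param path FASTA file, one record per TF (header = TF name).
#' @return named character vector of coding sequences.
#' @export
read_orf_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  .check_acgt(x, "ORF fasta")
  if (anyDuplicated(names(x)))
    stop("DuplicateName in ORF fasta", call. = FALSE)
  x
}

#' Read the vector junction context from a 2-record FASTA
#'
#' @param path FASTA with records named `upstream` and `downstream`.
#' @return list with elements `upstream` and `downstream`.
#' @export
read_vector_context <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- tolower(sub("\\s.*$", "", names(ss)))
  if (!all(c("upstream", "downstream") %in% nm))
    stop("vector FASTA must contain records named 'upstream' and 'downstream'",
         call. = FALSE)
  list(upstream = as.character(ss[[match("upstream", nm)]]),
       downstream = as.character(ss[[match("downstream", nm)]]))
}

#' Write / read a tag table as TSV
#'
#' @param x a tag table from [build_tag_table].
#' @param path file path.
#' @return `read_tag_table` returns the table; `write_tag_table` returns
#'   `path` invisibly.
#' @export
write_tag_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  out$extended <- as.logical(out$extended)
  class(out) <- c("tag_table", "data.frame")
  out
}
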