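#' Alignment helpers
#'
#' Alignments are represented as named character vectors of equal-length
#' strings over `A,C,G,T,N,-`.
#'
#' @param aln Named character vector (an alignment).
#' @return A character matrix, rows = sequences, columns = alignment columns.
#' @export
aln_matrix <- function(aln) {
  check_alignment(aln)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' @rdname aln_matrix
#' @param m Character matrix of single residues.
#' @export
matrix_aln <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

check_alignment <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1L, !is.null(names(aln)))
  if (anyDuplicated(names(aln))) stop("alignment IDs must be unique")
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows must all have the same length")
  }
  invisible(aln)
}

aln_dnabin <- function(aln) {
  ape::as.DNAbin(aln_matrix(tolower_aln(aln)))
}

tolower_aln <- function(aln) stats::setNames(tolower(aln), names(aln))

#' Drop gap-dominated alignment columns
#'
#' Keeps exactly the columns whose non-gap fraction is at least
#' `min_nongap_frac` (the trimming convention of trimal `-gt`). `N` counts as
#' a residue, not a gap.
#'
#' @param aln Alignment (named character vector).
#' @param min_nongap_frac Minimum fraction of non-gap residues per kept
#'   column (default 0.01).
#' @return The filtered alignment; attribute `kept_columns` holds the
#'   original column indices retained.
#' @export
filter_columns <- function(aln, min_nongap_frac = 0.01) {
  m <- aln_matrix(aln)
  frac <- colMeans(m != "-")
  keep <- which(frac >= min_nongap_frac)
  if (length(keep) == 0L) stop("all alignment columns removed by filtering")
  out <- matrix_aln(m[, keep, drop = FALSE])
  attr(out, "kept_columns") <- keep
  out
}

# Extract full gapped pattern/subject strings from a PairwiseAlignments
# object. The fast accessors pattern()/subject() can clip terminal gap
# regions of a global alignment; pairs failing a reconstruction check are
# re-extracted with the (slower) alignedPattern()/alignedSubject().
gapped_pairs <- function(pas, pattern_seqs, subject_seq) {
  p <- as.character(Biostrings::pattern(pas))
  s <- as.character(Biostrings::subject(pas))
  ok <- gsub("-", "", p, fixed = TRUE) == pattern_seqs &
    gsub("-", "", s, fixed = TRUE) == subject_seq
  if (!all(ok)) {
    bad <- which(!ok)
    p[bad] <- as.character(Biostrings::alignedPattern(pas[bad]))
    s[bad] <- as.character(Biostrings::alignedSubject(pas[bad]))
  }
  list(pattern = p, subject = s)
}

#' Reference-guided multiple alignment
#'
#' Aligns every sequence globally to a reference with
#' [Biostrings::pairwiseAlignment()] and merges the pairwise alignments into
#' one frame: insertions relative to the reference open shared gap columns.
#' This mirrors the common practice of aligning repeat copies against their
#' family consensus; it is not a full progressive MSA.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param reference Reference sequence (default: the longest input).
#' @param include_reference Add the reference as first alignment row?
#' @return An alignment (named character vector) over `A,C,G,T,N,-`.
#' @export
align_to_reference <- function(seqs, reference = NULL,
                               include_reference = FALSE) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (is.null(reference)) reference <- seqs[[which.max(nchar(seqs))]]
  L <- nchar(reference)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE
  )
  # one vectorized alignment call, then per sequence: residue (or '-') at
  # each reference position, plus the insertion string sitting after each
  # reference position (slot 0 = before)
  pas <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs), subject = reference,
    type = "global", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 1
  )
  ext <- gapped_pairs(pas, unname(seqs), reference)
  pat <- ext$pattern
  subj <- ext$subject
  per_seq <- lapply(seq_along(seqs), function(si) {
    p <- strsplit(pat[si], "")[[1]]
    r <- strsplit(subj[si], "")[[1]]
    base <- character(L)
    ins <- character(L + 1L)
    ins[] <- ""
    pos <- 0L
    for (k in seq_along(r)) {
      if (r[k] == "-") {
        ins[pos + 1L] <- paste0(ins[pos + 1L], p[k])
      } else {
        pos <- pos + 1L
        base[pos] <- p[k]
      }
    }
    list(base = base, ins = ins)
  })
  ins_len <- vapply(0:L, function(slot) {
    max(vapply(per_seq, function(x) nchar(x$ins[slot + 1L]), 0L))
  }, 0L)
  build_row <- function(base, ins) {
    parts <- character(2L * L + 1L)
    for (slot in 0:L) {
      g <- ins[slot + 1L]
      parts[2L * slot + 1L] <- paste0(g, strrep("-", ins_len[slot + 1L] - nchar(g)))
      if (slot < L) parts[2L * slot + 2L] <- base[slot + 1L]
    }
    paste(parts, collapse = "")
  }
  rows <- vapply(per_seq, function(x) build_row(x$base, x$ins), "")
  names(rows) <- names(seqs)
  if (include_reference) {
    ref_row <- build_row(strsplit(reference, "")[[1]], rep("", L + 1L))
    rows <- c(stats::setNames(ref_row, "reference"), rows)
  }
  check_alignment(rows)
}
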