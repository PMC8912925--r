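#' Read a FASTA file
#'
#' Reads DNA records, uppercases them and maps U to T so downstream code only
#' ever sees the alphabet `A,C,G,T,N,-`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record IDs).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ with 0-based half-open coordinates. Columns beyond the sixth are
#' ignored; name/score/strand are kept when present.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `strand`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1], " has fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("invalid BED interval at line ", bad[1], ": end must exceed start >= 0")
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 6L)) {
    strand <- vapply(fields, `[[`, "", 6L)
    out$strand <- ifelse(strand %in% c("+", "-"), strand, "+")
  }
  out
}

#' Write intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  df <- data.frame(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end)
  )
  has_name <- "name" %in% names(intervals)
  has_strand <- "strand" %in% names(intervals)
  if (has_name || has_strand) {
    df$name <- if (has_name) intervals$name else "."
    df$score <- 0L
    df$strand <- if (has_strand) intervals$strand else "+"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a newick tree with support labels
#'
#' Internal node labels that parse as numbers in `[0, 100]` are interpreted as
#' clade supports and normalized to `[0, 1]` (values above 1 are treated as
#' percentages). Missing branch lengths become 0.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` with numeric `node.label` supports in `[0, 1]`
#'   (NA where absent).
#' @export
read_tree <- function(path) {
  stopifnot(file.exists(path))
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("unparseable newick in ", path)
  normalize_supports(tr)
}

normalize_supports <- function(tr) {
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    sup[!is.na(sup) & sup > 1] <- sup[!is.na(sup) & sup > 1] / 100
    if (any(!is.na(sup) & (sup < 0 | sup > 1))) {
      stop("support values outside [0,1] after normalization")
    }
    tr$node.label <- sup
  }
  tr
}

#' Write a tree to newick
#'
#' Numeric node supports (in `[0, 1]`) are written as internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label)) {
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              format(tree$node.label, trim = TRUE))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a RepeatMasker-style annotation table
#'
#' A TSV with columns `chrom`, `start`, `end`, `strand`, `family`,
#' `element_id` (0-based half-open coordinates).
#'
#' @param path Path to the TSV.
#' @return A tibble of repeat annotations.
#' @export
read_repeat_table <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "start", "end", "strand", "family", "element_id")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) stop("annotation table lacks column(s): ",
                              paste(miss, collapse = ", "))
  stopifnot(all(ann$end > ann$start), all(ann$family != ""))
  ann
}

#' Assemble analyzable LTR elements from repeat annotations
#'
#' Classifies each LTR annotation as the 5' LTR of a full-length insertion or
#' as a solo LTR. An LTR immediately upstream (within `merge_gap`) of an
#' internal-region annotation on the same strand starts a candidate provirus;
#' if a downstream LTR closes the span within `merge_gap` and the merged
#' LTR-internal-LTR span exceeds `full_len_min`, the upstream LTR (in
#' transcriptional orientation) is kept as `five_prime_ltr` and the downstream
#' LTR is dropped. All other LTRs are `solo_ltr`. Only LTRs longer than
#' `min_ltr_len` are returned.
#'
#' @param annotations Tibble of repeat annotations (see [read_repeat_table()]).
#' @param ltr_families Character vector of family names counting as LTR.
#' @param internal_family Family name of the internal region.
#' @param genome Optional named character vector of chromosome sequences;
#'   when given, element sequences are extracted (minus-strand elements are
#'   reverse-complemented so all elements are in LTR orientation).
#' @param full_len_min Minimum merged provirus span in bp (default 4000).
#' @param min_ltr_len Minimum retained LTR length in bp (default 350;
#'   strictly greater than).
#' @param merge_gap Maximum gap in bp between adjacent LTR/internal pieces
#'   (default 500).
#' @return A tibble with `element_id`, `chrom`, `start`, `end`, `strand`,
#'   `structure` (`solo_ltr`/`five_prime_ltr`) and `sequence` (NA without a
#'   genome).
#' @export
assemble_elements <- function(annotations, ltr_families, internal_family,
                              genome = NULL, full_len_min = 4000,
                              min_ltr_len = 350, merge_gap = 500) {
  ann <- dplyr::as_tibble(annotations)
  dup <- duplicated(ann[, c("chrom", "start", "end", "strand", "family")])
  if (any(dup)) {
    warning(sum(dup), " duplicate annotation(s) removed")
    ann <- ann[!dup, ]
  }
  ann <- dplyr::arrange(ann, .data$chrom, .data$start)
  is_ltr <- ann$family %in% ltr_families
  is_int <- ann$family == internal_family
  structure <- rep(NA_character_, nrow(ann))
  drop <- rep(FALSE, nrow(ann))

  for (chr in unique(ann$chrom)) {
    idx <- which(ann$chrom == chr)
    for (i in idx[is_ltr[idx]]) {
      if (!is.na(structure[i]) || drop[i]) next
      # look for LTR -> internal -> LTR run on the same strand
      j <- idx[is_int[idx] & ann$strand[idx] == ann$strand[i] &
                 ann$start[idx] >= ann$end[i] &
                 ann$start[idx] - ann$end[i] <= merge_gap]
      if (length(j) > 0L) {
        j <- j[1]
        k <- idx[is_ltr[idx] & ann$strand[idx] == ann$strand[i] &
                   ann$start[idx] >= ann$end[j] &
                   ann$start[idx] - ann$end[j] <= merge_gap]
        if (length(k) > 0L) {
          k <- k[1]
          span <- ann$end[k] - ann$start[i]
          if (span > full_len_min) {
            # 5' LTR is upstream in transcriptional orientation
            five <- if (ann$strand[i] == "-") k else i
            three <- if (ann$strand[i] == "-") i else k
            structure[five] <- "five_prime_ltr"
            drop[three] <- TRUE
            next
          }
        }
      }
    }
  }
  structure[is_ltr & is.na(structure) & !drop] <- "solo_ltr"

  keep <- is_ltr & !drop & !is.na(structure) &
    (ann$end - ann$start) > min_ltr_len
  out <- ann[keep, c("element_id", "chrom", "start", "end", "strand")]
  out$structure <- structure[keep]
  out$sequence <- NA_character_
  if (!is.null(genome)) {
    out$sequence <- vapply(seq_len(nrow(out)), function(r) {
      s <- substr(genome[[out$chrom[r]]], out$start[r] + 1L, out$end[r])
      if (out$strand[r] == "-") s <- revcomp(s)
      toupper(s)
    }, "")
  }
  dplyr::as_tibble(out)
}

#' Reverse complement
#' @param seq A DNA string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
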