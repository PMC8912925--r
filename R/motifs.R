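#' Position weight matrices
#'
#' A PWM is a list with `name`, `matrix` (positions x `A,C,G,T`
#' probabilities, rows summing to 1) and `background` (default uniform).
#'
#' @param mat Numeric matrix, positions x 4 (columns A,C,G,T), of
#'   probabilities or counts.
#' @param name Motif name.
#' @param background Background base frequencies (default uniform).
#' @param counts Treat `mat` as counts and convert with pseudocount 0.5?
#' @return A `pwm` object.
#' @export
pwm <- function(mat, name = "pwm", background = rep(0.25, 4),
                counts = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4L)
  colnames(mat) <- c("A", "C", "G", "T")
  if (counts) mat <- (mat + 0.5) / rowSums(mat + 0.5)
  if (any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("PWM rows must sum to 1 (or pass counts = TRUE)")
  }
  structure(list(name = name, matrix = mat,
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T"))),
            class = "pwm")
}

#' Build a PWM from an exact motif string
#'
#' Convenience wrapper giving each motif base probability ~1 at its
#' position (with a small off-probability so log-odds stay finite).
#'
#' @param motif DNA string over `A,C,G,T`.
#' @param name Motif name (default the string itself).
#' @return A `pwm` object.
#' @export
pwm_from_string <- function(motif, name = motif) {
  motif <- toupper(motif)
  b <- strsplit(motif, "")[[1]]
  stopifnot(all(b %in% c("A", "C", "G", "T")))
  m <- matrix(1e-3 / 3, nrow = length(b), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, colnames(m)))] <- 1 - 1e-3
  pwm(m / rowSums(m), name = name)
}

#' Read PWMs from JASPAR or HOMER text files
#'
#' JASPAR: `>id name` then four `A|C|G|T [ counts ]` rows (counts are
#' converted with pseudocount 0.5). HOMER: `>consensus name ...` then one
#' whitespace-separated row of 4 probabilities per motif position.
#'
#' @param path Path to the motif file.
#' @param format `"auto"` (default), `"jaspar"` or `"homer"`.
#' @return A list of `pwm` objects.
#' @export
read_pwm <- function(path, format = c("auto", "jaspar", "homer")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (any(grepl("^[ACGT]\\s*\\[", lines))) "jaspar" else "homer"
  }
  heads <- which(startsWith(lines, ">"))
  stopifnot(length(heads) > 0L)
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(i) {
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    if (format == "jaspar") {
      name <- if (length(toks) >= 2L) toks[2] else toks[1]
      rows <- lapply(c("A", "C", "G", "T"), function(b) {
        ln <- body[startsWith(trimws(body), b)][1]
        as.numeric(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]", "", trimws(ln))),
                            "\\s+")[[1]])
      })
      pwm(t(do.call(rbind, rows)), name = name, counts = TRUE)
    } else {
      name <- if (length(toks) >= 2L) toks[2] else toks[1]
      rows <- do.call(rbind, lapply(body, function(ln)
        as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
      pwm(rows, name = name)
    }
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

pwm_score_matrix <- function(p, pseudo = 1e-3) {
  log2((p$matrix + pseudo) / matrix(p$background, nrow(p$matrix), 4,
                                    byrow = TRUE))
}

#' Scan a sequence with a PWM
#'
#' Log-odds scoring `sum(log2((p + 1e-3) / bg))` over every window on both
#' strands; windows containing `N` (or gaps) are skipped. Default hit
#' threshold is 80% of the maximal achievable score.
#'
#' @param sequence DNA string over `A,C,G,T,N` (gaps tolerated and
#'   skipped).
#' @param p A [pwm()].
#' @param threshold Log-odds hit threshold; default `0.8 * max score`.
#' @param both_strands Scan the reverse strand too? Default TRUE.
#' @return Tibble `position` (1-based start on the input), `strand`,
#'   `score`; zero rows if the PWM is longer than the sequence.
#' @export
scan_pwm <- function(sequence, p, threshold = NULL, both_strands = TRUE) {
  stopifnot(inherits(p, "pwm"))
  S <- pwm_score_matrix(p)
  w <- nrow(S)
  if (is.null(threshold)) threshold <- 0.8 * sum(apply(S, 1L, max))
  scan_one <- function(seq, strand) {
    x <- strsplit(toupper(gsub("-", "", seq)), "")[[1]]
    n <- length(x)
    if (n < w) return(NULL)
    idx <- match(x, c("A", "C", "G", "T"))
    nwin <- n - w + 1L
    sc <- numeric(nwin)
    bad <- logical(nwin)
    for (off in seq_len(w)) {
      v <- idx[off:(nwin + off - 1L)]
      na <- is.na(v)
      bad <- bad | na
      v[na] <- 1L
      sc <- sc + S[off, v]
    }
    keep <- which(!bad & sc >= threshold)
    if (length(keep) == 0L) return(NULL)
    pos <- keep
    if (strand == "-") pos <- n - (pos + w - 1L) + 1L
    tibble::tibble(position = as.integer(pos), strand = strand,
                   score = unname(sc[keep]))
  }
  seq_fwd <- gsub("-", "", toupper(sequence))
  out <- scan_one(seq_fwd, "+")
  if (both_strands && nchar(seq_fwd) >= w) {
    out <- dplyr::bind_rows(out, scan_one(revcomp(seq_fwd), "-"))
  }
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(position = integer(), strand = character(),
                          score = numeric()))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Per-element block sequences
#'
#' Slices a family element alignment into blocks and returns the degapped
#' per-element block sequences, the input shape for [block_enrichment()].
#'
#' @param aln Family alignment keyed by element ID.
#' @param partition A `subfamily_partition` or assignments tibble.
#' @param blocks Block definition tibble (`block`, `start`, `end`).
#' @return Tibble `element_id`, `subfamily`, `block`, `sequence`.
#' @export
block_sequences <- function(aln, partition, blocks) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  slices <- slice_blocks(aln, blocks)
  purrr::map_dfr(names(slices), function(bn) {
    tibble::tibble(element_id = names(slices[[bn]]), block = bn,
                   sequence = gsub("-", "", unname(slices[[bn]])))
  }) %>%
    dplyr::inner_join(asn, by = "element_id") %>%
    dplyr::filter(.data$subfamily != "unassigned", nzchar(.data$sequence)) %>%
    dplyr::select("element_id", "subfamily", "block", "sequence")
}

#' Block-wise pairwise motif enrichment
#'
#' ZOOPS counting (a sequence is a hit if it contains at least one PWM
#' match) with a one-sided hypergeometric test of target hits against the
#' pooled background, per motif and block.
#'
#' @param block_seqs Tibble from [block_sequences()].
#' @param pwms List of [pwm()] objects.
#' @param target Target subfamily.
#' @param background Character vector of background subfamilies (default:
#'   all others present).
#' @param cutoff Significance cutoff on the hypergeometric p (default
#'   1e-5).
#' @param min_n Minimum sequences required on each side (default 5; blocks
#'   below it are skipped).
#' @return Tibble `motif`, `block`, `target`, `background`,
#'   `n_target_hit`, `n_target`, `n_bg_hit`, `n_bg`, `p`, `passes_cutoff`,
#'   sorted by `p`.
#' @export
block_enrichment <- function(block_seqs, pwms, target, background = NULL,
                             cutoff = 1e-5, min_n = 5L) {
  stopifnot(target %in% block_seqs$subfamily)
  if (is.null(background)) {
    background <- setdiff(unique(block_seqs$subfamily), target)
  }
  bg_label <- paste(background, collapse = "+")
  res <- purrr::map_dfr(unique(block_seqs$block), function(bn) {
    tseq <- block_seqs$sequence[block_seqs$block == bn &
                                  block_seqs$subfamily == target]
    bseq <- block_seqs$sequence[block_seqs$block == bn &
                                  block_seqs$subfamily %in% background]
    if (length(tseq) < min_n || length(bseq) < min_n) return(NULL)
    purrr::map_dfr(pwms, function(p) {
      hit <- function(s) nrow(scan_pwm(s, p)) > 0L
      ht <- sum(vapply(tseq, hit, TRUE))
      hb <- sum(vapply(bseq, hit, TRUE))
      n_t <- length(tseq); n_b <- length(bseq)
      total_hit <- ht + hb
      pval <- if (total_hit == 0L || total_hit == n_t + n_b) {
        1
      } else {
        stats::phyper(ht - 1, total_hit, n_t + n_b - total_hit, n_t,
                      lower.tail = FALSE)
      }
      tibble::tibble(motif = p$name, block = bn, target = target,
                     background = bg_label, n_target_hit = ht,
                     n_target = n_t, n_bg_hit = hb, n_bg = n_b, p = pval,
                     passes_cutoff = pval <= cutoff)
    })
  })
  dplyr::arrange(res, .data$p)
}

#' All ordered pairwise block enrichments
#'
#' Runs [block_enrichment()] for every ordered (target, background)
#' subfamily pair within each block.
#'
#' @inheritParams block_enrichment
#' @return Row-bound enrichment tibble over all ordered pairs.
#' @export
block_enrichment_all <- function(block_seqs, pwms, cutoff = 1e-5,
                                 min_n = 5L) {
  sf <- sort(unique(block_seqs$subfamily))
  purrr::map_dfr(sf, function(tg) {
    purrr::map_dfr(setdiff(sf, tg), function(bg) {
      block_enrichment(block_seqs, pwms, target = tg, background = bg,
                       cutoff = cutoff, min_n = min_n)
    })
  })
}

#' Subfamily-specific insertions in a consensus alignment
#'
#' Maximal runs of alignment columns where the target consensus has bases
#' while every other listed consensus has gaps — candidate lineage-specific
#' insertions (such as the 8-bp promoter-motif gain studied in the worked
#' examples).
#'
#' @param aln Aligned consensus sequences.
#' @param target Target taxon name.
#' @param others Taxa required to be gapped (default: all other taxa).
#' @return Tibble `position` (1-based start in the degapped target),
#'   `length`, `insert`.
#' @export
find_subfamily_specific_insertions <- function(aln, target, others = NULL) {
  check_alignment(aln)
  if (is.null(others)) others <- setdiff(names(aln), target)
  stopifnot(target %in% names(aln), length(others) >= 1L)
  m <- aln_matrix(aln)
  tgt <- m[target, ]
  spec <- tgt != "-" &
    colSums(m[others, , drop = FALSE] != "-") == 0L
  if (!any(spec)) {
    return(tibble::tibble(position = integer(), length = integer(),
                          insert = character()))
  }
  r <- rle(spec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tgt_pos <- cumsum(tgt != "-")
  purrr::map_dfr(runs, function(i) {
    cols <- starts[i]:ends[i]
    tibble::tibble(position = tgt_pos[starts[i]],
                   length = length(cols),
                   insert = paste(tgt[cols], collapse = ""))
  })
}
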