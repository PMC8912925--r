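#' Slice a consensus alignment into sequence blocks
#'
#' @param aln Aligned consensus sequences (named character vector).
#' @param blocks Tibble with `block`, `start`, `end` (0-based half-open
#'   alignment columns, non-overlapping and ordered).
#' @return Named list of sub-alignments; each carries an `absent` attribute
#'   listing taxa that are entirely gaps within the block.
#' @export
slice_blocks <- function(aln, blocks) {
  check_alignment(aln)
  L <- nchar(aln[[1]])
  stopifnot(all(c("block", "start", "end") %in% names(blocks)))
  b <- dplyr::arrange(dplyr::as_tibble(blocks), .data$start)
  if (any(b$start >= b$end)) stop("empty or inverted block definition")
  if (any(b$start < 0L) || any(b$end > L)) stop("block outside alignment")
  if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)])) {
    stop("overlapping block definitions")
  }
  out <- lapply(seq_len(nrow(b)), function(i) {
    sl <- stats::setNames(substr(aln, b$start[i] + 1L, b$end[i]), names(aln))
    attr(sl, "absent") <- names(sl)[gsub("-", "", sl) == ""]
    sl
  })
  stats::setNames(out, b$block)
}

#' Per-block phylogenies with bootstrap support
#'
#' Builds one supported tree per sequence block, dropping taxa absent
#' (all-gap) from a block and skipping blocks with fewer than 4 present
#' taxa. `method = "nj"` uses distance trees with column-resampling
#' bootstrap; `method = "parsimony"` uses the parsimony ratchet per
#' replicate (slower, mirrors classic block-parsimony analysis). Gaps are
#' unknown states by default; set `gaps_as = "state"` for blocks whose
#' signal is carried by the indel itself.
#'
#' @param block_slices Output of [slice_blocks()].
#' @param method `"nj"` (default) or `"parsimony"`.
#' @param reps Bootstrap replicates (default 100).
#' @param gaps_as `"unknown"` or `"state"`, recycled over blocks.
#' @param seed Integer seed.
#' @return Named list of `ape::phylo` with numeric supports (skipped blocks
#'   are `NULL`).
#' @export
block_trees <- function(block_slices, method = c("nj", "parsimony"),
                        reps = 100, gaps_as = "unknown", seed = 1L) {
  method <- match.arg(method)
  gaps_as <- rep_len(gaps_as, length(block_slices))
  out <- vector("list", length(block_slices))
  names(out) <- names(block_slices)
  for (i in seq_along(block_slices)) {
    sl <- block_slices[[i]]
    present <- setdiff(names(sl), attr(sl, "absent"))
    if (length(present) < 4L) {
      warning("block ", names(block_slices)[i],
              ": fewer than 4 present taxa; skipped")
      next
    }
    sub <- sl[present]
    out[[i]] <- tryCatch({
      if (method == "nj") {
        # BIONJ per replicate: short blocks have noisy distances and the
        # variance-weighted join is markedly more stable there
        bootstrap_support(sub, reps = reps, seed = seed + i,
                          tree_method = "bionj")
      } else {
        parsimony_bootstrap(sub, reps = reps, gaps_as = gaps_as[i],
                            seed = seed + i)
      }
    }, error = function(e) {
      warning("block ", names(block_slices)[i], ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(out[[i]])) {
      attr(out[[i]], "alignment") <- sub
      attr(out[[i]], "gaps_as") <- gaps_as[i]
    }
  }
  out
}

parsimony_bootstrap <- function(aln, reps = 100, gaps_as = "unknown",
                                seed = 1L) {
  point <- parsimony_search(aln, gaps_as = gaps_as, seed = seed)
  m <- aln_matrix(aln)
  set.seed(seed)
  rep_trees <- lapply(seq_len(reps), function(b) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    parsimony_search(matrix_aln(m[, cols, drop = FALSE]), gaps_as = gaps_as,
                     seed = seed + b)
  })
  counts <- ape::prop.clades(point, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- counts / reps
  point
}

#' Detect phylogenetic incongruence between block trees and a reference
#'
#' For each block, every bipartition supported at `support_min` that cannot
#' coexist with the supported structure of the reference topology
#' (restricted to the taxa shared by both trees) is a recombination
#' candidate; reference splits with support below `support_min` are treated
#' as unresolved and cannot generate conflicts (splits without support
#' values are trusted). A bipartition and its
#' complement count once; overlapping conflicting clades within a block are
#' merged into a single event, so the returned count is a minimum number of
#' recombination events.
#'
#' @param btrees Named list of block trees (from [block_trees()]).
#' @param reference Reference `ape::phylo` (overall consensus topology).
#' @param support_min Minimum support for a conflicting clade (default
#'   0.95).
#' When block trees carry their alignment (as produced by [block_trees()]),
#' a character-evidence gate is applied: the block topology must explain
#' the block data strictly better than the reference under the Fitch
#' criterion (`min_score_gain` fewer steps). High bootstrap support can
#' arise from distance noise alone on short blocks; a genuine block
#' exchange always leaves sites that the reference topology cannot explain
#' as cheaply.
#'
#' @param ages Optional named numeric vector of subfamily ages (Mya); when
#'   given, the older lineage inside a conflicting clade is reported as the
#'   putative donor, otherwise direction is `"?"`.
#' @param min_score_gain Minimum parsimony improvement (steps) of the block
#'   tree over the reference on the block data (default 1); only applied
#'   when the block alignment is available.
#' @return Tibble `block`, `clade`, `support`, `conflicts_with`,
#'   `direction`, `classification` — one row per merged event.
#' @export
detect_incongruence <- function(btrees, reference, support_min = 0.95,
                                ages = NULL, min_score_gain = 1L) {
  events <- tibble::tibble(block = character(), clade = character(),
                           support = numeric(), conflicts_with = character(),
                           direction = character(),
                           classification = character())
  for (bn in names(btrees)) {
    bt <- btrees[[bn]]
    if (is.null(bt)) next
    shared <- intersect(bt$tip.label, reference$tip.label)
    if (length(shared) < 4L) next
    bt_s <- ape::keep.tip(bt, shared)
    # keep.tip on the block tree preserves numeric node supports
    ref_s <- ape::keep.tip(reference, shared)
    block_aln <- attr(bt, "alignment")
    if (!is.null(block_aln)) {
      ga <- attr(bt, "gaps_as")
      if (is.null(ga)) ga <- "unknown"
      gain <- fitch_score(block_aln[shared], ref_s, gaps_as = ga) -
        fitch_score(block_aln[shared], bt_s, gaps_as = ga)
      if (gain < min_score_gain) next
    }
    ref_all <- tree_splits(ref_s)
    # a conflict only counts against reference structure that is itself
    # supported; weak reference splits are NJ noise, not topology
    ref_sup <- Filter(function(r) is.na(r$support) ||
                        r$support >= support_min, ref_all)
    ref_splits <- lapply(ref_sup, `[[`, "tips")
    conflicts <- list()
    for (s in tree_splits(bt_s)) {
      if (is.na(s$support) || s$support < support_min) next
      bad <- NULL
      for (r in ref_splits) {
        if (!splits_compatible(s$tips, r, shared)) {
          bad <- r
          break
        }
      }
      if (is.null(bad)) next
      side <- s$tips
      other <- setdiff(shared, side)
      small <- if (length(side) <= length(other)) side else other
      key <- split_key(s$tips, shared)
      if (!key %in% vapply(conflicts, `[[`, "", "key")) {
        conflicts[[length(conflicts) + 1L]] <- list(
          key = key, clade = small, support = s$support,
          ref = split_key(bad, shared)
        )
      }
    }
    if (length(conflicts) == 0L) next
    # merge overlapping conflicting clades into one event
    grp <- seq_along(conflicts)
    for (i in seq_along(conflicts)) {
      for (j in seq_along(conflicts)) {
        if (i < j && length(intersect(conflicts[[i]]$clade,
                                      conflicts[[j]]$clade)) > 0L) {
          grp[grp == grp[j]] <- grp[i]
        }
      }
    }
    for (g in unique(grp)) {
      members <- conflicts[grp == g]
      rep_cl <- members[[which.max(vapply(members, `[[`, 0, "support"))]]
      direction <- "?"
      if (!is.null(ages) && all(rep_cl$clade %in% names(ages))) {
        donor <- rep_cl$clade[which.max(ages[rep_cl$clade])]
        direction <- paste0(donor, "->",
                            paste(setdiff(rep_cl$clade, donor),
                                  collapse = "+"))
      }
      events <- dplyr::add_row(events, block = bn,
                               clade = paste(rep_cl$clade, collapse = ","),
                               support = rep_cl$support,
                               conflicts_with = rep_cl$ref,
                               direction = direction,
                               classification = "recombination_candidate")
    }
  }
  events
}

#' Test two consensus blocks for tandem duplication
#'
#' Globally aligns the two block sequences (match +1, mismatch -1, gap open
#' 2, gap extend 1) and computes nucleotide identity over aligned columns
#' excluding terminal gaps. A duplication is called when identity reaches
#' `min_identity` and the blocks are adjacent in the block table.
#'
#' @param consensus Consensus sequence in the block coordinate frame
#'   (alignment frame string, gaps allowed).
#' @param blocks Block definition tibble (`block`, `start`, `end`).
#' @param block_i,block_j Names of the two blocks to compare.
#' @param min_identity Identity threshold for a call (default 0.70).
#' @return One-row tibble `block_i`, `block_j`, `identity`, `adjacent`,
#'   `call`; zero rows if either block is absent (all gaps).
#' @export
detect_duplication <- function(consensus, blocks, block_i, block_j,
                               min_identity = 0.70) {
  b <- dplyr::as_tibble(blocks)
  stopifnot(all(c(block_i, block_j) %in% b$block))
  seg <- function(name) {
    r <- b[b$block == name, ]
    gsub("[-N]", "", substr(consensus, r$start + 1L, r$end))
  }
  si <- seg(block_i); sj <- seg(block_j)
  if (!nzchar(si) || !nzchar(sj)) {
    return(tibble::tibble(block_i = character(), block_j = character(),
                          identity = numeric(), adjacent = logical(),
                          call = logical()))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    pattern = si, subject = sj, type = "global",
    substitutionMatrix = submat, gapOpening = 2, gapExtension = 1
  )
  gp <- gapped_pairs(pa, si, sj)
  p <- strsplit(gp$pattern, "")[[1]]
  q <- strsplit(gp$subject, "")[[1]]
  inner <- which(p != "-" & q != "-")
  span <- seq(min(inner), max(inner))
  identity <- sum(p[span] == q[span] & p[span] != "-") / length(span)
  bi <- match(block_i, b$block); bj <- match(block_j, b$block)
  adjacent <- abs(bi - bj) == 1L
  tibble::tibble(block_i = block_i, block_j = block_j, identity = identity,
                 adjacent = adjacent,
                 call = identity >= min_identity && adjacent)
}

#' Sliding-window breakpoint scan (advisory)
#'
#' Builds a supported NJ tree per window and reports positions where a
#' clade supported in one window is incompatible with a clade supported in
#' the next — candidate recombination breakpoints. Block definitions remain
#' the analyst's call; this is a screening aid.
#'
#' @param aln Aligned consensus sequences.
#' @param window Window width in columns.
#' @param step Step between windows (default `window / 2`).
#' @param support_min Support threshold (default 0.95).
#' @param reps Bootstrap replicates per window (default 50).
#' @param seed Integer seed.
#' @return Tibble `position` (boundary column between the two windows),
#'   `left_clade`, `right_clade`.
#' @export
scan_breakpoints <- function(aln, window, step = NULL, support_min = 0.95,
                             reps = 50, seed = 1L) {
  check_alignment(aln)
  L <- nchar(aln[[1]])
  if (window > L) stop("window larger than alignment (", L, " columns)")
  if (is.null(step)) step <- max(1L, window %/% 2L)
  starts <- seq(0L, L - window, by = step)
  taxa <- names(aln)
  win_splits <- lapply(seq_along(starts), function(i) {
    sub <- stats::setNames(substr(aln, starts[i] + 1L, starts[i] + window),
                           taxa)
    tr <- tryCatch(bootstrap_support(sub, reps = reps, seed = seed + i,
                                     tree_method = "bionj"),
                   error = function(e) NULL)
    if (is.null(tr)) return(list())
    Filter(function(s) !is.na(s$support) && s$support >= support_min,
           tree_splits(tr))
  })
  out <- tibble::tibble(position = integer(), left_clade = character(),
                        right_clade = character())
  # compare consecutive informative windows; windows without any supported
  # split carry no topology signal and are skipped
  inf <- which(lengths(win_splits) > 0L)
  if (length(inf) >= 2L) {
    for (ii in seq_len(length(inf) - 1L)) {
      i <- inf[ii]; j <- inf[ii + 1L]
      boundary <- as.integer((starts[i] + starts[j] + window) %/% 2L)
      for (a in win_splits[[i]]) {
        for (b in win_splits[[j]]) {
          if (!splits_compatible(a$tips, b$tips, taxa)) {
            out <- dplyr::add_row(out, position = boundary,
                                  left_clade = paste(a$tips, collapse = ","),
                                  right_clade = paste(b$tips, collapse = ","))
          }
        }
      }
    }
  }
  dplyr::distinct(out)
}
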