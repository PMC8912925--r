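#' Pairwise distances from an alignment
#'
#' Raw (p) or Jukes-Cantor distances with pairwise deletion: alignment
#' columns containing a gap or `N` in either member of a pair are excluded
#' for that pair.
#'
#' @param aln Alignment (named character vector).
#' @param model `"p"` for raw proportion of differing sites, `"jc"` for the
#'   Jukes-Cantor correction \eqn{-\frac{3}{4}\log(1 - 4p/3)}.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("p", "jc")) {
  model <- match.arg(model)
  check_alignment(aln)
  if (length(aln) < 2L) stop("need at least 2 sequences")
  d <- ape::dist.dna(aln_dnabin(aln),
                     model = if (model == "p") "raw" else "JC69",
                     pairwise.deletion = TRUE)
  m <- as.matrix(d)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("no comparable columns (or saturated distance) for pair ",
         rownames(m)[bad[1]], " / ", colnames(m)[bad[2]])
  }
  m
}

#' Neighbor-joining tree
#'
#' Standard NJ via [ape::nj()], or the variance-weighted BIONJ variant
#' ([ape::bionj()]) which is more stable on short alignments where distance
#' estimates are noisy. Negative branch lengths are clamped to 0.
#'
#' @param dist Symmetric distance matrix (n >= 3).
#' @param method `"nj"` (default) or `"bionj"`.
#' @return An unrooted `ape::phylo`.
#' @export
nj_tree <- function(dist, method = c("nj", "bionj")) {
  method <- match.arg(method)
  m <- as.matrix(dist)
  if (any(is.na(m) | is.nan(m))) stop("NaN/NA in distance matrix")
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  tr <- if (method == "bionj") ape::bionj(m) else ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' NJ tree with column-resampling bootstrap supports
#'
#' Builds the point-estimate NJ tree, then resamples alignment columns
#' `reps` times, rebuilds an NJ tree per replicate and attaches to each
#' internal node the fraction of replicates containing the same bipartition.
#'
#' @param aln Alignment (named character vector).
#' @param reps Number of bootstrap replicates (default 100).
#' @param model Distance model, see [pairwise_distance()].
#' @param seed Optional integer seed for the resampling RNG.
#' @param tree_method Tree builder per replicate, see [nj_tree()].
#' @return An `ape::phylo` with numeric `node.label` supports in `[0, 1]`.
#' @export
bootstrap_support <- function(aln, reps = 100, model = "p", seed = NULL,
                              tree_method = "nj") {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  point <- nj_tree(pairwise_distance(aln, model), method = tree_method)
  m_low <- aln_matrix(tolower_aln(aln))
  nc <- ncol(m_low)
  ape_model <- if (model == "p") "raw" else "JC69"
  rep_trees <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_trees[[b]] <- tryCatch({
      d <- as.matrix(ape::dist.dna(ape::as.DNAbin(m_low[, cols, drop = FALSE]),
                                   model = ape_model,
                                   pairwise.deletion = TRUE))
      if (any(!is.finite(d))) stop("incomparable pair in replicate")
      nj_tree(d, method = tree_method)
    }, error = function(e) NULL)
  }
  rep_trees <- Filter(Negate(is.null), rep_trees)
  counts <- ape::prop.clades(point, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- counts / length(rep_trees)
  point
}

#' Fitch small-parsimony score
#'
#' Sums the minimal number of state changes over all alignment columns on a
#' fixed topology. By default gaps and `N` are unknown states (compatible
#' with anything); `gaps_as = "state"` treats `-` as a fifth character state
#' (used for alignment blocks that are entirely indel-coded).
#'
#' @param aln Alignment covering all tree leaves.
#' @param tree An `ape::phylo`; leaf labels must be alignment IDs.
#' @param gaps_as `"unknown"` (default) or `"state"`.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(aln, tree, gaps_as = c("unknown", "state")) {
  gaps_as <- match.arg(gaps_as)
  miss <- setdiff(tree$tip.label, names(aln))
  if (length(miss) > 0L) {
    stop("tree leaves without sequence: ", paste(miss, collapse = ", "))
  }
  dat <- phydat_from_aln(aln[tree$tip.label], gaps_as)
  tr <- ape::multi2di(ape::unroot(tree))
  as.integer(phangorn::fitch(tr, dat))
}

phydat_from_aln <- function(aln, gaps_as) {
  m <- aln_matrix(tolower_aln(aln))
  if (gaps_as == "unknown") {
    m[m == "-" | m == "n"] <- "?"
    phangorn::phyDat(m, type = "DNA")
  } else {
    m[m == "n"] <- "?"
    phangorn::phyDat(m, type = "USER",
                     levels = c("a", "c", "g", "t", "-"), ambiguity = "?")
  }
}

#' Heuristic maximum-parsimony tree search
#'
#' Parsimony ratchet ([phangorn::pratchet()]) over the Fitch criterion;
#' designed for small taxon sets such as subfamily consensus sequences.
#'
#' @inheritParams fitch_score
#' @param seed Integer seed making the search deterministic.
#' @param ... Passed to [phangorn::pratchet()].
#' @return An unrooted `ape::phylo`; attribute `pscore` holds its Fitch score.
#' @export
parsimony_search <- function(aln, gaps_as = c("unknown", "state"),
                             seed = 1L, ...) {
  gaps_as <- match.arg(gaps_as)
  check_alignment(aln)
  n <- length(aln)
  if (n < 4L) {
    tr <- ape::read.tree(
      text = paste0("(", paste(names(aln), collapse = ","), ");")
    )
    attr(tr, "pscore") <- if (n >= 2L)
      fitch_score(aln, if (n == 2L) tr else ape::unroot(tr), gaps_as) else 0L
    return(tr)
  }
  dat <- phydat_from_aln(aln, gaps_as)
  set.seed(seed)
  tr <- suppressWarnings(
    phangorn::pratchet(dat, trace = 0, all = FALSE, ...)
  )
  tr <- ape::unroot(tr)
  attr(tr, "pscore") <- as.integer(phangorn::fitch(tr, dat))
  tr
}

# ---- bipartition utilities -------------------------------------------------

# All non-trivial bipartitions of an (un)rooted tree as a list with the
# descendant tip-label set of each internal edge, plus that edge's support
# and length. Root-adjacent duplicates are collapsed.
tree_splits <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 1]), integer(0))
  nodes <- setdiff(seq_len(ntip + nnode)[-seq_len(ntip)], root)
  sup <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$node.label) && length(tree$node.label) == nnode) {
    lab <- tree$node.label
    if (!is.numeric(lab)) lab <- suppressWarnings(as.numeric(lab))
    sup[ntip + seq_len(nnode)] <- lab
  }
  len <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$edge.length)) {
    len[tree$edge[, 2]] <- tree$edge.length
  }
  out <- lapply(nodes, function(nd) {
    list(tips = sort(desc[[nd]]), support = sup[nd], length = len[nd],
         node = nd)
  })
  # drop trivial splits (all tips or all but one)
  out[vapply(out, function(s) {
    k <- length(s$tips); k >= 2L && k <= ntip - 2L
  }, TRUE)]
}

# canonical key for a bipartition given the full taxon set: the side not
# containing the alphabetically first taxon, sorted and collapsed
split_key <- function(tips, all_taxa) {
  anchor <- min(all_taxa)
  side <- if (anchor %in% tips) sort(setdiff(all_taxa, tips)) else sort(tips)
  paste(side, collapse = "|")
}

# are two bipartitions (given as tip sets over the same taxon universe)
# compatible, i.e. can they coexist on one tree?
splits_compatible <- function(a, b, all_taxa) {
  a2 <- setdiff(all_taxa, a)
  b2 <- setdiff(all_taxa, b)
  length(intersect(a, b)) == 0L || length(intersect(a, b2)) == 0L ||
    length(intersect(a2, b)) == 0L || length(intersect(a2, b2)) == 0L
}
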