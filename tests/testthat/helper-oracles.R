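# Independent oracles used across the suite. These deliberately use naive
# enumeration / all-pairs algorithms, never the package's own fast paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# expected observed differences after a Poisson substitution process with
# d expected events/site (Jukes-Cantor saturation)
jc_expected_diffs <- function(d, L) L * 0.75 * (1 - exp(-4 * d / 3))

# exhaustive small-parsimony score: minimize changes over all assignments
# of states to internal nodes (and to unknown tips)
enum_parsimony <- function(aln, tree, gaps_as = "unknown") {
  states <- if (gaps_as == "state") c("A", "C", "G", "T", "-") else
    c("A", "C", "G", "T")
  tr <- ape::multi2di(ape::unroot(tree))
  m <- do.call(rbind, strsplit(aln[tr$tip.label], ""))
  ntip <- nrow(m)
  nnode <- tr$Nnode
  total <- 0L
  for (col in seq_len(ncol(m))) {
    x <- m[, col]
    unknown <- if (gaps_as == "state") x == "N" else x %in% c("-", "N")
    free <- c(which(unknown), ntip + seq_len(nnode))
    fixed <- stats::setNames(x, seq_len(ntip))
    combos <- expand.grid(rep(list(states), length(free)),
                          stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign <- fixed
      assign[as.character(free)] <- unlist(combos[r, ])
      cost <- sum(assign[as.character(tr$edge[, 1])] !=
                    assign[as.character(tr$edge[, 2])])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# all three unrooted quartet topologies over four names
quartet_topologies <- function(nm) {
  list(
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));", nm[1], nm[2], nm[3], nm[4])),
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));", nm[1], nm[3], nm[2], nm[4])),
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));", nm[1], nm[4], nm[2], nm[3]))
  )
}

# Prim MST total length on a distance matrix
mst_length <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  intree <- c(1L)
  total <- 0
  while (length(intree) < n) {
    out <- setdiff(seq_len(n), intree)
    sub <- d[intree, out, drop = FALSE]
    total <- total + min(sub)
    j <- out[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    intree <- c(intree, j)
  }
  total
}

hamming_mat <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- sum(states[i, ] != states[j, ])
  }
  d
}

# brute-force minimum total length of a median-augmented spanning network:
# optimal Steiner points in Hamming space can be chosen per site among the
# observed states, and <= n - 2 of them suffice for n terminals
steiner_min_length <- function(states, max_medians = max(0L, nrow(states) - 2L)) {
  site_states <- lapply(seq_len(ncol(states)), function(j) unique(states[, j]))
  cand <- as.matrix(expand.grid(site_states, stringsAsFactors = FALSE))
  keys <- apply(states, 1, paste, collapse = "")
  cand <- cand[!apply(cand, 1, paste, collapse = "") %in% keys, ,
               drop = FALSE]
  best <- mst_length(hamming_mat(states))
  for (k in seq_len(max_medians)) {
    if (nrow(cand) < k) break
    combos <- utils::combn(nrow(cand), k)
    for (ci in seq_len(ncol(combos))) {
      aug <- rbind(states, cand[combos[, ci], , drop = FALSE])
      best <- min(best, mst_length(hamming_mat(aug)))
    }
  }
  best
}

# total length of a built network, as the MST over its node set
net_total_length <- function(net) mst_length(hamming_mat(net$states))

# exact two-sided Wilcoxon rank-sum p by full enumeration
wilcox_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# naive all-pairs overlap in bp of each element with the peak set
naive_overlap_bp <- function(elements, peaks) {
  vapply(seq_len(nrow(elements)), function(i) {
    pos <- integer(0)
    pk <- peaks[peaks$chrom == elements$chrom[i], ]
    for (j in seq_len(nrow(pk))) {
      lo <- max(elements$start[i], pk$start[j])
      hi <- min(elements$end[i], pk$end[j])
      if (hi > lo) pos <- union(pos, seq(lo, hi - 1L))
    }
    length(pos)
  }, 0L)
}

# convenience: true-label ARI for a recovered partition
partition_ari <- function(part, truth) {
  asn <- part$assignments
  true <- truth$elements$subfamily[match(asn$element_id,
                                         truth$elements$element_id)]
  mclust::adjustedRandIndex(asn$subfamily, true)
}

# family simulation -> supported NJ tree (shared by several tests)
sim_family_tree <- function(truth, reps = 100, seed = 1) {
  seqs <- stats::setNames(truth$elements$sequence,
                          truth$elements$element_id)
  aln <- filter_columns(align_to_reference(seqs))
  list(aln = aln,
       tree = bootstrap_support(aln, reps = reps, seed = seed))
}

# most divergent backbone founder pair for a given simulator seed (the
# detectable planted-recombination scenario: swaps between sisters leave no
# incongruence to find)
pick_recomb_pair <- function(seed, n_subfamilies = 8) {
  bb <- simulate_family(sim_config(seed = seed,
                                   n_subfamilies = n_subfamilies,
                                   copies_per_subfamily = 1))$backbone
  d <- ape::cophenetic.phylo(bb)
  idx <- which(d == max(d), arr.ind = TRUE)[1, ]
  c(rownames(d)[idx[1]], colnames(d)[idx[2]])
}

# identity of a consensus to the true founder over non-N consensus positions
consensus_founder_identity <- function(consensus, founder) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(consensus, founder, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- p %in% c("A", "C", "G", "T") & q %in% c("A", "C", "G", "T")
  sum(p[ok] == q[ok]) / sum(ok)
}

# seven-block grid over a family alignment, with internal boundaries shifted
# by half a block when one would cut through the planted motif's columns in
# the target consensus (blocks are analyst input; an analyst draws them
# around such features, never through them)
motif_safe_blocks <- function(aln, truth, motif_pwm, target = "sf01",
                              n_blocks = 7L) {
  L <- nchar(aln[[1]])
  ids_t <- truth$elements$element_id[truth$elements$subfamily == target]
  cons_t <- majority_consensus(aln[ids_t])
  hit <- scan_pwm(as.character(cons_t), motif_pwm, both_strands = FALSE)
  b <- round(seq(0, L, length.out = n_blocks + 1L))
  if (nrow(hit) > 0L) {
    w <- nrow(motif_pwm$matrix)
    frame <- attr(cons_t, "frame")
    span <- range(frame[hit$position[1]:(hit$position[1] + w - 1L)])
    # a 0-based boundary at x cuts 1-based columns span[1]..span[2] iff
    # span[1] <= x <= span[2] - 1
    cuts <- function(x) x >= span[1] & x <= span[2] - 1L
    inner <- b[-c(1L, length(b))]
    if (any(cuts(inner))) {
      inner <- pmin(L - 1L, inner + round(L / n_blocks / 2))
    }
    inner <- inner[!cuts(inner)]
    b <- unique(c(0L, inner, L))
  }
  tibble::tibble(block = sprintf("b%d", seq_len(length(b) - 1L)),
                 start = as.integer(b[-length(b)]),
                 end = as.integer(b[-1]))
}
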