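test_that("column filtering keeps exactly columns at the non-gap threshold", {
  aln <- c(a = "A-CA", b = "A-C-", c = "A--A")
  out <- filter_columns(aln, 0.01)
  expect_equal(unname(out), c("ACA", "AC-", "A-A"), ignore_attr = TRUE)
  expect_equal(attr(out, "kept_columns"), c(1L, 3L, 4L))

  # exactly at threshold is kept: 1 non-gap in 100 rows at gt 0.01
  rows <- c("AA", rep("A-", 99))
  names(rows) <- paste0("s", seq_along(rows))
  kept <- filter_columns(rows, 0.01)
  expect_equal(nchar(kept[[1]]), 2L)

  expect_equal(unname(filter_columns(aln, 0)), unname(aln),
               ignore_attr = TRUE)
  allgap <- c(a = "--", b = "--")
  expect_error(filter_columns(allgap), "removed")
})

test_that("pairwise distances follow p and JC closed forms with pairwise deletion", {
  aln <- c(a = "AAAA", b = "AAAT")
  expect_equal(pairwise_distance(aln, "p")["a", "b"], 0.25)
  expect_equal(pairwise_distance(aln, "jc")["a", "b"],
               -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-4)
  expect_equal(round(pairwise_distance(aln, "jc")["a", "b"], 4), 0.3041)

  ident <- c(a = "ACGT", b = "ACGT")
  expect_equal(pairwise_distance(ident, "p")["a", "b"], 0)

  # gap/N columns dropped per pair
  g <- c(a = "A-GT", b = "ACGA")
  expect_equal(pairwise_distance(g, "p")["a", "b"], 1 / 3)
  # no comparable columns errors with the pair named
  bad <- c(a = "A---", b = "-CGT", c = "ACGT")
  expect_error(pairwise_distance(bad, "p"), "a.*b|b.*a")
})

test_that("NJ solves the 3-taxon closed form and recovers additive trees", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # x = (dab + dac - dbc)/2 etc.
  bl <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))

  # additive 4-taxon matrix from ((a,b),(c,d))
  tru <- ape::read.tree(text = "((a:1,b:2):3,(c:1,d:2):0);")
  d4 <- ape::cophenetic.phylo(tru)
  tr4 <- nj_tree(d4)
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(tru)), 0,
               ignore_attr = TRUE)

  dn <- d; dn[1, 2] <- NaN
  expect_error(nj_tree(dn), "NaN")
})

test_that("bootstrap supports separate real clusters and stay in bounds", {
  set.seed(10)
  anc <- rand_dna(300)
  left <- mutate_sequence(anc, 0.2)
  mk_burst <- function(f, pre, n) {
    stats::setNames(vapply(seq_len(n), function(i)
      mutate_sequence(f, 0.01), ""), paste0(pre, seq_len(n)))
  }
  aln <- c(mk_burst(anc, "L", 5), mk_burst(left, "R", 5))
  tr <- bootstrap_support(aln, reps = 100, seed = 1)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 1, na.rm = TRUE))
  sep <- Filter(function(s) setequal(s$tips, paste0("L", 1:5)) ||
                  setequal(s$tips, paste0("R", 1:5)),
                phyloreg:::tree_splits(tr))
  expect_gt(length(sep), 0)
  expect_gte(max(vapply(sep, `[[`, 0, "support")), 0.95)

  # reps = 1 gives supports in {0, 1}
  tr1 <- bootstrap_support(aln, reps = 1, seed = 2)
  expect_true(all(tr1$node.label %in% c(0, 1), na.rm = TRUE))

  # supports do not depend on leaf order
  perm <- sample(names(aln))
  trp <- bootstrap_support(aln[perm], reps = 100, seed = 1)
  key <- function(t) {
    s <- phyloreg:::tree_splits(t)
    stats::setNames(vapply(s, `[[`, 0, "support"),
                    vapply(s, function(x)
                      phyloreg:::split_key(x$tips, t$tip.label), ""))
  }
  k1 <- key(tr); k2 <- key(trp)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0)
  expect_equal(k1[shared], k2[shared], tolerance = 0.12)
})

test_that("no-signal alignments do not produce confident clades", {
  set.seed(11)
  base <- rand_dna(200)
  aln <- stats::setNames(vapply(1:8, function(i)
    mutate_sequence(base, 0.3), ""), paste0("t", 1:8))
  # shuffle columns independently to destroy any residual structure
  m <- aln_matrix(aln)
  m <- apply(m, 2, sample)
  rownames(m) <- paste0("t", 1:8)
  tr <- bootstrap_support(matrix_aln(m), reps = 100, seed = 3)
  expect_lt(mean(tr$node.label, na.rm = TRUE), 0.95)
})

test_that("Fitch score equals exhaustive parsimony, in both gap modes", {
  expect_equal(fitch_score(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
                           quartet_topologies(letters[1:4])[[1]]), 0L)
  expect_equal(fitch_score(c(a = "A", b = "-", c = "A", d = "A"),
                           quartet_topologies(letters[1:4])[[1]]), 0L)

  set.seed(12)
  for (rep in 1:5) {
    n <- sample(4:5, 1)
    nm <- letters[seq_len(n)]
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * 6, replace = TRUE,
                       prob = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1)), nrow = n)
    rownames(m) <- nm
    aln <- matrix_aln(m)
    topo <- if (n == 4) quartet_topologies(nm)[[sample(3, 1)]] else
      ape::rtree(n, tip.label = sample(nm))
    expect_equal(fitch_score(aln, topo, "unknown"),
                 enum_parsimony(aln, topo, "unknown"))
    expect_equal(fitch_score(aln, topo, "state"),
                 enum_parsimony(aln, topo, "state"))
  }
})

test_that("parsimony search matches the exhaustive quartet optimum and is seeded", {
  set.seed(13)
  for (rep in 1:3) {
    aln <- stats::setNames(vapply(1:4, function(i) rand_dna(40), ""),
                           letters[1:4])
    best_enum <- min(vapply(quartet_topologies(letters[1:4]),
                            function(t) fitch_score(aln, t), 0L))
    tr <- parsimony_search(aln, seed = 5)
    expect_equal(attr(tr, "pscore"), best_enum)
    tr2 <- parsimony_search(aln, seed = 5)
    expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
  }
  # high-signal 8-taxon recovery
  set.seed(14)
  anc <- rand_dna(400)
  tru <- ape::rtree(8, tip.label = paste0("t", 1:8))
  tru$edge.length <- rep(0.06, nrow(tru$edge))
  seqs <- vector("list", 8 + tru$Nnode)
  seqs[[9]] <- anc
  tru <- ape::reorder.phylo(tru, "cladewise")
  for (e in seq_len(nrow(tru$edge))) {
    seqs[[tru$edge[e, 2]]] <- mutate_sequence(seqs[[tru$edge[e, 1]]], 0.06)
  }
  aln <- stats::setNames(unlist(seqs[1:8]), tru$tip.label)
  fit <- parsimony_search(aln, seed = 2)
  expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(tru)), 0,
               ignore_attr = TRUE)
})
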