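make_supported_tree <- function(text) {
  phyloreg:::normalize_supports(ape::read.tree(text = text))
}

test_that("star trees and unsupported trees yield no subfamilies", {
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:20, ":0.1", collapse = ","), ");"
  ))
  star$node.label <- numeric(0)
  star <- phyloreg:::normalize_supports(star)
  p <- partition_tree(star)
  expect_equal(nrow(p$clades), 0L)
  expect_true(all(p$assignments$subfamily == "unassigned"))

  nolab <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  nolab$node.label <- NULL
  expect_error(partition_tree(nolab), "bootstrap")
})

test_that("clade size rule is strict: 10 members rejected, 11 accepted", {
  mk <- function(k) {
    inner <- paste0(paste0("c", 1:k, ":0.001", collapse = ","))
    out <- paste0(paste0("o", 1:12, ":0.001", collapse = ","))
    make_supported_tree(sprintf("((%s)1.0:0.05,%s);", inner, out))
  }
  p10 <- partition_tree(mk(10))
  expect_false(any(grepl("^c", p10$assignments$element_id) &
                     p10$assignments$subfamily != "unassigned"))
  p11 <- partition_tree(mk(11))
  expect_equal(sum(p11$assignments$subfamily != "unassigned" &
                     grepl("^c", p11$assignments$element_id)), 11L)
})

test_that("branch length rule is strict and thresholds are monotone", {
  mk <- function(len) {
    inner <- paste0(paste0("c", 1:12, ":0.001", collapse = ","))
    out <- paste0(paste0("o", 1:12, ":0.001", collapse = ","))
    make_supported_tree(sprintf("((%s)1.0:%g,%s);", inner, len, out))
  }
  expect_equal(nrow(partition_tree(mk(0.015))$clades), 0L)
  expect_gt(nrow(partition_tree(mk(0.016))$clades), 0L)

  # raising size_min / branch_min never adds clades
  cfg <- sim_config(seed = 31, n_subfamilies = 4, copies_per_subfamily = 15)
  st <- sim_family_tree(simulate_family(cfg), reps = 60, seed = 31)
  base <- nrow(partition_tree(st$tree)$clades)
  for (sm in c(10, 14)) {
    for (bm in c(0.015, 0.03)) {
      expect_lte(nrow(partition_tree(st$tree, size_min = sm,
                                     branch_min = bm)$clades), base)
    }
  }
})

test_that("partitions are invariant to re-rooting", {
  cfg <- sim_config(seed = 32, n_subfamilies = 3, copies_per_subfamily = 15)
  st <- sim_family_tree(simulate_family(cfg), reps = 60, seed = 32)
  p1 <- partition_tree(st$tree)
  rerooted <- ape::root(st$tree, outgroup = st$tree$tip.label[1],
                        resolve.root = TRUE, edgelabel = TRUE)
  p2 <- partition_tree(rerooted)
  # same clusters regardless of names
  m1 <- stats::setNames(p1$assignments$subfamily, p1$assignments$element_id)
  m2 <- stats::setNames(p2$assignments$subfamily, p2$assignments$element_id)
  expect_equal(mclust::adjustedRandIndex(m1, m2[names(m1)]), 1)
})

test_that("majority consensus follows the 51% rule with N and gap deletion", {
  aln3 <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_equal(as.character(majority_consensus(aln3)), "ACGT")

  # 50/50 column is not a majority at 0.51
  tie <- stats::setNames(c(rep("A", 5), rep("T", 5)), paste0("s", 1:10))
  expect_equal(as.character(majority_consensus(tie)), "N")

  # plurality gap deletes the column; frame records surviving columns
  gap <- c(a = "A-C", b = "A-C", c = "AGC")
  cons <- majority_consensus(gap)
  expect_equal(as.character(cons), "AC")
  expect_equal(attr(cons, "frame"), c(1L, 3L))
  expect_equal(attr(cons, "aligned"), "A-C")

  # consensus of a single sequence is that sequence
  one <- c(x = "ACGTN")
  expect_equal(as.character(majority_consensus(one)), "ACGTN")
  expect_error(majority_consensus(character(0)))
})

test_that("nearest-consensus assignment is exact on consensuses and tie-broken by name", {
  cons <- c(alpha = "ACGTACGTACGT", beta = "ACGTACGTTTTT")
  self <- assign_by_similarity(cons, cons)
  expect_equal(self$subfamily, c("alpha", "beta"))
  expect_equal(self$distance, c(0, 0))

  # equidistant sequence goes to the lexicographically first name
  eq <- c(q = "ACGTACGTACTT")
  res <- assign_by_similarity(eq, cons)
  expect_equal(res$subfamily, "alpha")
})

test_that("terminal-branch age tests: null calm, separated waves detected, exact p", {
  # exact Wilcoxon against enumeration on a tiny case
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  wt <- stats::wilcox.test(x, y)
  expect_equal(wt$p.value, 0.1)
  expect_equal(wilcox_exact_p(x, y), 0.1)

  # two waves with very different terminal rates separate sharply
  cfg <- sim_config(seed = 33, n_subfamilies = 4, copies_per_subfamily = 50,
                    terminal_branch_subs = c(0.005, 0.005, 0.02, 0.02),
                    indel_rate = 0)
  tr <- simulate_family(cfg)
  st <- sim_family_tree(tr, reps = 1, seed = 33)
  part <- tibble::tibble(element_id = tr$elements$element_id,
                         subfamily = tr$elements$subfamily)
  grouping <- c(sf01 = "young", sf02 = "young", sf03 = "old", sf04 = "old")
  ag <- age_groups(st$tree, part, grouping)
  expect_lt(ag$tests$padj[1], 1e-6)

  # identical distributions: padj stays high
  cfg0 <- sim_config(seed = 34, n_subfamilies = 2, copies_per_subfamily = 40,
                     terminal_branch_subs = 0.01, indel_rate = 0)
  tr0 <- simulate_family(cfg0)
  st0 <- sim_family_tree(tr0, reps = 1, seed = 34)
  ag0 <- age_groups(st0$tree,
                    tibble::tibble(element_id = tr0$elements$element_id,
                                   subfamily = tr0$elements$subfamily),
                    c(sf01 = "g1", sf02 = "g2"))
  expect_gt(ag0$tests$padj[1], 0.05)

  # a group with < 2 members reports NA
  tiny <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  agNA <- age_groups(tiny, tibble::tibble(
    element_id = c("a", "b", "c", "d"),
    subfamily = c("x", "x", "x", "y")
  ), c(x = "gx", y = "gy"))
  expect_true(is.na(agNA$tests$p[1]))
})

test_that("orthology profiles match the uniform-age expectation", {
  part <- tibble::tibble(element_id = paste0("e", 1:4),
                         subfamily = "S1")
  pres <- tibble::tibble(element_id = paste0("e", 1:4),
                         chimp = c(1L, 1L, 1L, 1L),
                         macaque = c(0L, 0L, 0L, 0L))
  prof <- orthology_profile(pres, part, c("chimp", "macaque"))
  expect_equal(prof$fraction[prof$species == "chimp"], 1)
  expect_equal(prof$fraction[prof$species == "macaque"], 0)

  # ages uniform on (4, 10), split at 6 -> expected shared fraction 2/3
  cfg <- sim_config(seed = 35, n_subfamilies = 1, copies_per_subfamily = 300,
                    activity_windows = list(c(10, 4)))
  tr <- simulate_family(cfg)
  prof2 <- orthology_profile(tr$presence,
                             tibble::tibble(
                               element_id = tr$elements$element_id,
                               subfamily = tr$elements$subfamily))
  expect_equal(prof2$fraction[prof2$species == "chimp"], 2 / 3,
               tolerance = 0.1)

  # unknown elements dropped with a warning
  part_extra <- dplyr::add_row(part, element_id = "ghost", subfamily = "S1")
  expect_warning(orthology_profile(pres, part_extra), "missing")
})

test_that("simulated families are recovered at the published thresholds", {
  cfg <- sim_config(seed = 36, copies_per_subfamily = 20)
  tr <- simulate_family(cfg)
  st <- sim_family_tree(tr, reps = 80, seed = 36)
  part <- partition_tree(st$tree)
  expect_gte(partition_ari(part, tr), 0.95)
  # every planted subfamily with > size_min members maps to exactly one clade
  tab <- table(tr$elements$subfamily,
               part$assignments$subfamily[match(tr$elements$element_id,
                                                part$assignments$element_id)])
  recovered <- apply(tab, 1, function(r) sum(r > 0) == 1 &&
                       !colnames(tab)[which(r > 0)] %in% "unassigned")
  expect_true(all(recovered))
})
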