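test_that("block slicing reproduces the alignment and flags absent taxa", {
  aln <- c(a = "ACGTACGT", b = "AC--ACGT", c = "AC----GT")
  blocks <- tibble::tibble(block = c("b1", "b2"), start = c(0L, 4L),
                           end = c(4L, 8L))
  sl <- slice_blocks(aln, blocks)
  expect_equal(paste0(sl$b1, sl$b2), unname(aln), ignore_attr = TRUE)

  aln2 <- c(a = "ACGTACGT", b = "----ACGT")
  sl2 <- slice_blocks(aln2, blocks)
  expect_equal(attr(sl2$b1, "absent"), "b")
  expect_equal(attr(sl2$b2, "absent"), character(0))

  expect_error(slice_blocks(aln, tibble::tibble(block = "x", start = 2L,
                                                end = 2L)), "empty")
  expect_error(slice_blocks(aln, tibble::tibble(block = c("x", "y"),
                                                start = c(0L, 3L),
                                                end = c(4L, 8L))),
               "overlap")
  expect_error(slice_blocks(aln, tibble::tibble(block = "x", start = 0L,
                                                end = 99L)), "outside")
})

test_that("quartet incongruence is found exactly once, symmetric in orientation", {
  ref <- phyloreg:::normalize_supports(
    ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1);")
  )
  same <- detect_incongruence(list(b1 = ref), ref)
  expect_equal(nrow(same), 0L)

  swapped <- phyloreg:::normalize_supports(
    ape::read.tree(text = "((A:1,C:1)100:1,(B:1,D:1)100:1);")
  )
  ev <- detect_incongruence(list(b1 = swapped), ref)
  expect_equal(nrow(ev), 1L)
  expect_setequal(strsplit(ev$clade, ",")[[1]], c("A", "C"))

  # unsupported conflict is ignored
  weak <- phyloreg:::normalize_supports(
    ape::read.tree(text = "((A:1,C:1)60:1,(B:1,D:1)60:1);")
  )
  expect_equal(nrow(detect_incongruence(list(b1 = weak), ref)), 0L)
})

test_that("planted block swaps are recovered in the right block with donor+acceptor", {
  hits <- 0L
  n_seeds <- 5L
  for (sd in seq_len(n_seeds)) {
    pr <- pick_recomb_pair(300 + sd)
    cfg <- sim_config(seed = 300 + sd, n_subfamilies = 8,
                      copies_per_subfamily = 1,
                      recomb_events = list(list(donor = pr[1],
                                                acceptor = pr[2],
                                                block = 3)))
    tr <- simulate_family(cfg)
    sl <- slice_blocks(tr$founder_aln, tr$blocks_aln)
    btr <- block_trees(sl, method = "nj", reps = 100, seed = sd)
    reftree <- bootstrap_support(tr$founder_aln, reps = 100, seed = sd + 500)
    ev <- detect_incongruence(btr, reftree)
    ok <- any(ev$block == "b3" &
                vapply(strsplit(ev$clade, ","), function(cl)
                  all(pr %in% cl) || all(cl %in% pr), TRUE))
    if (ok) hits <- hits + 1L
  }
  expect_equal(hits, n_seeds)
})

test_that("recombination-free simulations produce no events", {
  n_ev <- 0L
  for (sd in 1:5) {
    cfg <- sim_config(seed = 600 + sd, n_subfamilies = 8,
                      copies_per_subfamily = 1)
    tr <- simulate_family(cfg)
    sl <- slice_blocks(tr$founder_aln, tr$blocks_aln)
    btr <- block_trees(sl, method = "nj", reps = 100, seed = sd)
    reftree <- bootstrap_support(tr$founder_aln, reps = 100, seed = sd + 700)
    n_ev <- n_ev + nrow(detect_incongruence(btr, reftree))
  }
  expect_equal(n_ev, 0L)
})

test_that("duplication calls: identical blocks, diverged copies, random controls", {
  s <- paste0(strrep("ACGTT", 12), strrep("ACGTT", 12))
  blocks <- tibble::tibble(block = c("2a", "2b"), start = c(0L, 60L),
                           end = c(60L, 120L))
  d <- detect_duplication(s, blocks, "2a", "2b")
  expect_equal(d$identity, 1)
  expect_true(d$call)

  # non-adjacent blocks are not called even at high identity
  blocks3 <- tibble::tibble(block = c("2a", "mid", "2b"),
                            start = c(0L, 60L, 80L), end = c(60L, 80L, 140L))
  s3 <- paste0(strrep("ACGTT", 12), rand_dna(20), strrep("ACGTT", 12))
  d3 <- detect_duplication(s3, blocks3, "2a", "2b")
  expect_false(d3$call)

  # unrelated random blocks never reach the 0.70 threshold
  set.seed(50)
  ids <- replicate(60, {
    s2 <- paste0(rand_dna(60), rand_dna(60))
    detect_duplication(s2, blocks, "2a", "2b")$identity
  })
  expect_true(all(ids < 0.70))
  expect_gt(mean(ids), 0.25)
  expect_lt(mean(ids), 0.55)

  # absent block yields no call row
  gappy <- paste0(strrep("-", 60), rand_dna(60))
  expect_equal(nrow(detect_duplication(gappy, blocks, "2a", "2b")), 0L)
})

test_that("post-duplication divergence of 0.1 subs/site lands near 81% identity", {
  set.seed(51)
  ids <- vapply(1:30, function(i) {
    cfg <- sim_config(seed = 800 + i, n_subfamilies = 2,
                      copies_per_subfamily = 1,
                      dup_event = list(subfam = "sf01", block = 4))
    tr <- simulate_family(cfg)
    b <- tr$blocks[4, ]
    len <- b$end - b$start
    div <- mutate_sequence(tr$founders[["sf01"]], 0.1)
    blocks2 <- tibble::tibble(block = c("2a", "2b"),
                              start = c(b$start, b$end),
                              end = c(b$end, b$end + len))
    detect_duplication(div, blocks2, "2a", "2b")$identity
  }, 0)
  expect_gt(mean(ids), 0.70)
  expect_lt(mean(ids), 0.92)
  expect_gte(mean(ids >= 0.70), 0.9)
})

test_that("breakpoint scan flags a planted breakpoint and stays quiet otherwise", {
  cfg <- sim_config(seed = 52, n_subfamilies = 8, copies_per_subfamily = 1,
                    recomb_events = list(list(donor = "sf01",
                                              acceptor = "sf05",
                                              block = 5)))
  tr <- simulate_family(cfg)
  b5 <- tr$blocks[5, ]
  bp <- scan_breakpoints(tr$founder_aln, window = 64, step = 16,
                         reps = 60, seed = 2)
  expect_gt(nrow(bp), 0)
  expect_true(any(abs(bp$position - b5$start) <= 64 |
                    abs(bp$position - b5$end) <= 64))

  # window equal to the alignment: a single window, no candidates
  L <- nchar(tr$founder_aln[[1]])
  expect_equal(nrow(scan_breakpoints(tr$founder_aln, window = L,
                                     reps = 20, seed = 3)), 0L)
  expect_error(scan_breakpoints(tr$founder_aln, window = L + 1), "larger")

  # no recombination, no candidates
  cfg0 <- sim_config(seed = 53, n_subfamilies = 8, copies_per_subfamily = 1)
  tr0 <- simulate_family(cfg0)
  bp0 <- scan_breakpoints(tr0$founder_aln, window = 64, step = 16,
                          reps = 60, seed = 4)
  expect_equal(nrow(bp0), 0L)
})
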