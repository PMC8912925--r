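test_that("PWM constructors validate and parse both text dialects", {
  m <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  p <- pwm(m, "uniform")
  expect_s3_class(p, "pwm")
  expect_error(pwm(m * 2), "sum to 1")

  jf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    ">MA0001.1 TESTMOTIF",
    "A [ 10  0  0 ]",
    "C [  0 10  0 ]",
    "G [  0  0 10 ]",
    "T [  0  0  0 ]"
  ), jf)
  pj <- read_pwm(jf)
  expect_equal(names(pj), "TESTMOTIF")
  expect_equal(nrow(pj[[1]]$matrix), 3L)
  expect_equal(unname(pj[[1]]$matrix[1, "A"]), 10.5 / 12, tolerance = 1e-9)

  hf <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(
    ">ACG homer_test 5.0",
    "0.97 0.01 0.01 0.01",
    "0.01 0.97 0.01 0.01",
    "0.01 0.01 0.97 0.01"
  ), hf)
  ph <- read_pwm(hf)
  expect_equal(names(ph), "homer_test")
  expect_equal(unname(ph[[1]]$matrix[2, "C"]), 0.97)
})

test_that("scanner hits the consensus at full score; uniform PWMs score zero", {
  p <- pwm_from_string("ACGTACGT")
  hits <- scan_pwm("ACGTACGT", p)
  expect_true(any(hits$position == 1L & hits$strand == "+"))
  smax <- sum(apply(phyloreg:::pwm_score_matrix(p), 1, max))
  expect_equal(max(hits$score), smax, tolerance = 1e-9)

  uni <- pwm(matrix(0.25, 4, 4), "uniform")
  hits_u <- scan_pwm("ACGTACGTAC", uni, threshold = -1)
  expect_true(all(abs(hits_u$score - 4 * log2((0.25 + 1e-3) / 0.25)) < 1e-9))

  # longer PWM than sequence: no hits
  expect_equal(nrow(scan_pwm("ACG", p)), 0L)
  # windows containing N are skipped
  expect_equal(nrow(scan_pwm("ACGNACGT", pwm_from_string("ACGT"),
                             both_strands = FALSE)), 1L)
})

test_that("scanner equals the brute-force per-window oracle", {
  set.seed(60)
  seq <- rand_dna(50)
  p <- pwm_from_string("ACGT")
  S <- phyloreg:::pwm_score_matrix(p)
  x <- strsplit(seq, "")[[1]]
  oracle <- vapply(seq_len(47), function(s) {
    sum(S[cbind(1:4, match(x[s:(s + 3)], c("A", "C", "G", "T")))])
  }, 0)
  got <- scan_pwm(seq, p, threshold = -Inf, both_strands = FALSE)
  expect_equal(got$score, unname(oracle))
  expect_equal(got$position, seq_len(47))
})

test_that("hit sets are strand-symmetric under reverse complement", {
  set.seed(61)
  seq <- rand_dna(80)
  p <- pwm_from_string("CATTGT")
  fwd <- scan_pwm(seq, p, threshold = 0)
  rcseq <- revcomp(seq)
  rev <- scan_pwm(rcseq, p, threshold = 0)
  mirror <- sort(nchar(seq) - (rev$position + 6 - 1) + 1)
  expect_equal(sort(fwd$position), mirror)
  expect_setequal(round(fwd$score, 9), round(rev$score, 9))
})

test_that("hypergeometric enrichment matches exact enumeration and finds planted motifs", {
  # 10/10 target hits vs 0/10 background: p = 1 / choose(20, 10)
  bs <- tibble::tibble(
    element_id = paste0("e", 1:20),
    subfamily = rep(c("T", "B"), each = 10),
    block = "b1",
    sequence = c(replicate(10, paste0(rand_dna(10), "CATTGTTA", rand_dna(10))),
                 replicate(10, rand_dna(28)))
  )
  p <- pwm_from_string("CATTGTTA")
  res <- block_enrichment(bs, list(p), target = "T", background = "B")
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$passes_cutoff)

  # identical hit rates: p >= 0.5
  bs_null <- bs
  bs_null$sequence <- rep(paste0(rand_dna(4), "CATTGTTA", rand_dna(4)), 20)
  res_null <- block_enrichment(bs_null, list(p), target = "T",
                               background = "B")
  expect_gte(res_null$p, 0.5)

  # degenerate all-hit and no-hit cases give p = 1
  bs_none <- bs
  bs_none$sequence <- replicate(20, rand_dna(30))
  expect_equal(block_enrichment(bs_none, list(p), "T", "B")$p, 1)
})

test_that("planted motif gains are the top block enrichment in simulations", {
  top_ok <- 0L
  n_seeds <- 5L
  for (sd in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 900 + sd, copies_per_subfamily = 20,
                      motif_gain = list(subfam = "sf01",
                                        motif = "CATTGTTA", position = 200))
    tr <- simulate_family(cfg)
    seqs <- stats::setNames(tr$elements$sequence, tr$elements$element_id)
    aln <- filter_columns(align_to_reference(seqs))
    blocks <- phyloreg:::sim_block_table(nchar(aln[[1]]), 7)
    bs <- block_sequences(aln, tr$elements[, c("element_id", "subfamily")],
                          blocks)
    en <- block_enrichment(bs, list(pwm_from_string("CATTGTTA", "planted"),
                                    pwm_from_string("GGGCGGAA", "decoy")),
                           target = "sf01")
    if (en$motif[1] == "planted" && en$passes_cutoff[1]) top_ok <- top_ok + 1L
  }
  expect_equal(top_ok, n_seeds)
})

test_that("subfamily-specific insertion detection handles sharing", {
  aln <- c(t = "ACGTTTACGT", o1 = "ACG---ACGT", o2 = "ACG---ACGT")
  ins <- find_subfamily_specific_insertions(aln, "t")
  expect_equal(ins$position, 4L)
  expect_equal(ins$insert, "TTT")

  # shared with one other taxon: nothing against the full set,
  # found again once the sharer is excluded
  aln2 <- c(t = "ACGTTTACGT", sharer = "ACGTTTACGT", o = "ACG---ACGT")
  expect_equal(nrow(find_subfamily_specific_insertions(aln2, "t")), 0L)
  expect_equal(nrow(find_subfamily_specific_insertions(aln2, "t",
                                                       others = "o")), 1L)

  # no specific columns
  expect_equal(nrow(find_subfamily_specific_insertions(
    c(a = "ACGT", b = "ACGT"), "a")), 0L)

  # simulated 8-bp founder insertion is recovered exactly
  cfg <- sim_config(seed = 70, motif_gain = list(subfam = "sf02",
                                                 motif = "CATTGTTA",
                                                 position = 123))
  tr <- simulate_family(cfg)
  ins8 <- find_subfamily_specific_insertions(tr$founder_aln, "sf02")
  expect_equal(nrow(ins8), 1L)
  expect_equal(ins8$length, 8L)
  expect_equal(ins8$position, 124L)
  expect_equal(ins8$insert, "CATTGTTA")
})
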