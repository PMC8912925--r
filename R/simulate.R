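#' Simulation configuration for a synthetic LTR family
#'
#' Encodes the evolutionary model the package is tested against: founders of
#' `n_subfamilies` subfamilies diverge along a random backbone tree
#' (`backbone_branch_subs` substitutions/site per edge), optionally exchange
#' sequence blocks (recombination), tandem-duplicate a block, or gain a short
#' motif; each founder then emits a star-burst of copies with exponentially
#' distributed terminal branch lengths (mean `terminal_branch_subs`). Binary
#' regulatory marks are Bernoulli draws conditioned on subfamily; insertion
#' ages are uniform within per-subfamily activity windows and determine
#' orthologous presence across a species tree.
#'
#' Default activity windows follow the three observed waves of LTR7-like
#' amplification (roughly 25-40, 9-20 and 4-10 Mya); default species splits
#' approximate the great-ape/Old-World-monkey divergence ladder.
#'
#' @param seed Integer RNG seed.
#' @param ancestor_len Ancestral LTR length in bp (default 450).
#' @param n_subfamilies Number of subfamilies (default 8).
#' @param copies_per_subfamily Integer vector (recycled) of copies per
#'   subfamily; default samples 20-40 per subfamily.
#' @param backbone_branch_subs Substitutions/site per backbone edge
#'   (default 0.05).
#' @param terminal_branch_subs Mean substitutions/site on terminal branches
#'   (default 0.01); a vector is recycled over subfamilies, letting waves
#'   of different ages coexist.
#' @param indel_rate Indel events/site/branch on terminal branches
#'   (default 5e-4); lengths are geometric with mean 3.
#' @param n_blocks Number of equal sequence blocks in the ancestor frame
#'   (default 7).
#' @param recomb_events List of `list(donor=, acceptor=, block=)` applied to
#'   founders before their bursts (block index 1-based).
#' @param dup_event Optional `list(subfam=, block=)`: tandem-duplicate that
#'   block in the named founder.
#' @param motif_gain Optional `list(subfam=, motif=, position=)`: insert
#'   `motif` after `position` bp in the named founder.
#' @param mark_probs Named list: mark -> numeric vector of per-subfamily
#'   Bernoulli probabilities (recycled). Default: one subfamily-restricted
#'   activation mark and one evenly spread enhancer-like mark.
#' @param activity_windows List (recycled) of `c(start_mya, end_mya)` with
#'   `start > end`; defaults place subfamilies into three waves.
#' @param species_splits Named numeric vector of species divergence times
#'   (Mya).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       ancestor_len = 450L,
                       n_subfamilies = 8L,
                       copies_per_subfamily = NULL,
                       backbone_branch_subs = 0.05,
                       terminal_branch_subs = 0.01,
                       indel_rate = 5e-4,
                       n_blocks = 7L,
                       recomb_events = list(),
                       dup_event = NULL,
                       motif_gain = NULL,
                       mark_probs = NULL,
                       activity_windows = NULL,
                       species_splits = c(chimp = 6, gorilla = 9,
                                          orangutan = 16, gibbon = 20,
                                          macaque = 25)) {
  k <- as.integer(n_subfamilies)
  stopifnot(k >= 1L, ancestor_len >= n_blocks, backbone_branch_subs >= 0,
            terminal_branch_subs >= 0, indel_rate >= 0)
  if (is.null(activity_windows)) {
    wave <- list(c(40, 25), c(20, 9), c(10, 4))
    activity_windows <- wave[(ceiling(seq_len(k) * 3 / k))]
  } else if (!is.list(activity_windows)) {
    activity_windows <- list(activity_windows)
  }
  activity_windows <- rep_len(activity_windows, k)
  stopifnot(all(vapply(activity_windows, function(w) w[1] > w[2], TRUE)))
  if (is.null(mark_probs)) {
    mark_probs <- list(
      activation = c(0.9, rep(0.1, max(0L, k - 1L))),
      enhancer = rep(0.2, k)
    )
  }
  mark_probs <- lapply(mark_probs, function(p) {
    p <- rep_len(p, k)
    stopifnot(all(p >= 0 & p <= 1))
    p
  })
  if (!is.null(copies_per_subfamily)) {
    copies_per_subfamily <- rep_len(as.integer(copies_per_subfamily), k)
    stopifnot(all(copies_per_subfamily >= 1L))
  }
  structure(list(
    seed = as.integer(seed), ancestor_len = as.integer(ancestor_len),
    n_subfamilies = k, copies_per_subfamily = copies_per_subfamily,
    backbone_branch_subs = backbone_branch_subs,
    terminal_branch_subs = terminal_branch_subs,
    indel_rate = indel_rate, n_blocks = as.integer(n_blocks),
    recomb_events = recomb_events, dup_event = dup_event,
    motif_gain = motif_gain, mark_probs = mark_probs,
    activity_windows = activity_windows, species_splits = species_splits
  ), class = "sim_config")
}

#' Mutate a sequence along a branch
#'
#' Substitutions are a Poisson number of events (`branch_subs * length`),
#' each hitting a uniform site and replacing its base by one of the three
#' others; repeated hits at a site make the realized divergence follow the
#' Jukes-Cantor saturation curve \eqn{p = \frac{3}{4}(1 - e^{-4d/3})}.
#' Indel events are Poisson(`indel_rate * length`), insertion or deletion
#' with equal probability, lengths geometric with mean 3.
#'
#' @param seq DNA string.
#' @param branch_subs Expected substitutions/site on the branch.
#' @param indel_rate Indel events/site (default 0).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, branch_subs, indel_rate = 0) {
  stopifnot(branch_subs >= 0, indel_rate >= 0)
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- stats::rpois(1L, branch_subs * length(x))
  if (n_sub > 0L) {
    sites <- sample.int(length(x), n_sub, replace = TRUE)
    for (s in sites) {
      x[s] <- sample(setdiff(bases, x[s]), 1L)
    }
  }
  n_indel <- stats::rpois(1L, indel_rate * length(x))
  for (i in seq_len(n_indel)) {
    len <- stats::rgeom(1L, 1 / 3) + 1L
    if (stats::runif(1L) < 0.5 && length(x) > len) {
      at <- sample.int(length(x) - len + 1L, 1L)
      x <- x[-(at:(at + len - 1L))]
    } else {
      at <- sample.int(length(x) + 1L, 1L)
      x <- append(x, sample(bases, len, replace = TRUE), after = at - 1L)
    }
  }
  paste(x, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sim_block_table <- function(len, n_blocks) {
  edges <- round(seq(0L, len, length.out = n_blocks + 1L))
  tibble::tibble(
    block = sprintf("b%d", seq_len(n_blocks)),
    start = as.integer(edges[-length(edges)]),
    end = as.integer(edges[-1])
  )
}

#' Simulate an LTR family with known ground truth
#'
#' Runs the generative model described in [sim_config()] and returns an
#' `ltr_truth` object holding the elements, their true subfamily labels,
#' founder sequences, recorded recombination/duplication/motif events, ages,
#' orthologous-presence matrix and binary mark matrix.
#'
#' @param config A [sim_config()].
#' @return An `ltr_truth` list with components `elements` (tibble),
#'   `founders` (named character), `founder_aln` (the exact founder MSA:
#'   planted insertions open gap columns in non-carriers), `backbone`
#'   (`ape::phylo`), `blocks` / `blocks_aln` (block table in ancestor and
#'   founder-MSA frames), `events`, `marks`, `presence` (tibbles) and
#'   `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_subfamilies
  subfams <- sprintf("sf%02d", seq_len(k))
  blocks <- sim_block_table(config$ancestor_len, config$n_blocks)
  for (ev in config$recomb_events) {
    if (ev$block < 1L || ev$block > nrow(blocks)) {
      stop("recombination block index out of range: ", ev$block)
    }
  }
  if (!is.null(config$dup_event) &&
      (config$dup_event$block < 1L || config$dup_event$block > nrow(blocks))) {
    stop("duplication block index out of range: ", config$dup_event$block)
  }

  ancestor <- random_dna(config$ancestor_len)
  # founders along a random backbone topology, substitutions only so the
  # ancestor block frame stays valid for planted events
  if (k == 1L) {
    founders <- stats::setNames(ancestor, subfams)
    backbone <- NULL
  } else if (k == 2L) {
    backbone <- ape::read.tree(text = sprintf("(%s:1,%s:1);", subfams[1], subfams[2]))
    founders <- stats::setNames(
      vapply(subfams, function(s) mutate_sequence(ancestor,
                                                  config$backbone_branch_subs), ""),
      subfams)
  } else {
    backbone <- ape::rtopology(k, rooted = TRUE, tip.label = subfams)
    backbone$edge.length <- rep(config$backbone_branch_subs,
                                nrow(backbone$edge))
    backbone <- ape::reorder.phylo(backbone, "cladewise")
    nseq <- vector("list", k + backbone$Nnode)
    nseq[[k + 1L]] <- ancestor
    for (e in seq_len(nrow(backbone$edge))) {
      p <- backbone$edge[e, 1]; ch <- backbone$edge[e, 2]
      nseq[[ch]] <- mutate_sequence(nseq[[p]], config$backbone_branch_subs)
    }
    founders <- stats::setNames(unlist(nseq[seq_len(k)]), backbone$tip.label)
    founders <- founders[subfams]
  }

  events <- tibble::tibble(type = character(), subfamily = character(),
                           donor = character(), block = character(),
                           start = integer(), end = integer(),
                           detail = character())
  # planted events modify founders before the bursts
  for (ev in config$recomb_events) {
    b <- blocks[ev$block, ]
    substr(founders[[ev$acceptor]], b$start + 1L, b$end) <-
      substr(founders[[ev$donor]], b$start + 1L, b$end)
    events <- dplyr::add_row(events, type = "recombination",
                             subfamily = ev$acceptor, donor = ev$donor,
                             block = b$block, start = b$start, end = b$end,
                             detail = "")
  }
  # founder-specific insertions (duplication, motif gain), recorded in
  # ancestor coordinates and applied right-to-left so positions stay valid;
  # founder_aln keeps the exact founder MSA (gap columns for non-carriers)
  ins_ops <- list()
  if (!is.null(config$dup_event)) {
    de <- config$dup_event
    b <- blocks[de$block, ]
    seg <- substr(founders[[de$subfam]], b$start + 1L, b$end)
    ins_ops[[length(ins_ops) + 1L]] <- list(pos = b$end, seg = seg,
                                            carrier = de$subfam)
    events <- dplyr::add_row(events, type = "duplication",
                             subfamily = de$subfam, donor = de$subfam,
                             block = b$block, start = b$start, end = b$end,
                             detail = sprintf("copy at %d-%d", b$end,
                                              b$end + nchar(seg)))
  }
  if (!is.null(config$motif_gain)) {
    mg <- config$motif_gain
    ins_ops[[length(ins_ops) + 1L]] <- list(pos = as.integer(mg$position),
                                            seg = toupper(mg$motif),
                                            carrier = mg$subfam)
    events <- dplyr::add_row(events, type = "motif_gain",
                             subfamily = mg$subfam, donor = "",
                             block = "", start = as.integer(mg$position),
                             end = as.integer(mg$position + nchar(mg$motif)),
                             detail = toupper(mg$motif))
  }
  founder_aln <- founders
  blocks_aln <- blocks
  if (length(ins_ops) > 0L) {
    ord <- order(-vapply(ins_ops, `[[`, 0L, "pos"))
    for (op in ins_ops[ord]) {
      len <- nchar(op$seg)
      for (sf in names(founders)) {
        piece <- if (sf == op$carrier) op$seg else strrep("-", len)
        founder_aln[[sf]] <- paste0(substr(founder_aln[[sf]], 1L, op$pos),
                                    piece,
                                    substr(founder_aln[[sf]], op$pos + 1L,
                                           nchar(founder_aln[[sf]])))
      }
      f <- founders[[op$carrier]]
      founders[[op$carrier]] <- paste0(substr(f, 1L, op$pos), op$seg,
                                       substr(f, op$pos + 1L, nchar(f)))
      shift_start <- blocks_aln$start >= op$pos
      inside <- !shift_start & blocks_aln$end >= op$pos
      blocks_aln$start[shift_start] <- blocks_aln$start[shift_start] + len
      blocks_aln$end[shift_start | inside] <-
        blocks_aln$end[shift_start | inside] + len
    }
  }

  copies <- config$copies_per_subfamily
  if (is.null(copies)) copies <- sample(20:40, k, replace = TRUE)

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    w <- config$activity_windows[[i]]
    n_i <- copies[i]
    term_i <- rep_len(config$terminal_branch_subs, k)[i]
    tbl <- if (term_i == 0) rep(0, n_i) else
      stats::rexp(n_i, rate = 1 / term_i)
    seqs <- vapply(tbl, function(t)
      mutate_sequence(founders[[subfams[i]]], t, config$indel_rate), "")
    rows[[i]] <- tibble::tibble(
      element_id = sprintf("%s_e%03d", subfams[i], seq_len(n_i)),
      subfamily = subfams[i],
      sequence = seqs,
      terminal_subs = tbl,
      age_mya = stats::runif(n_i, min = w[2], max = w[1])
    )
  }
  el <- dplyr::bind_rows(rows)
  gaps <- 1000L
  lens <- nchar(el$sequence)
  el$chrom <- "chrSim"
  el$start <- as.integer(cumsum(c(0L, lens[-length(lens)] + gaps)))
  el$end <- el$start + lens
  el$strand <- "+"
  el$structure <- "solo_ltr"

  marks <- tibble::tibble(element_id = el$element_id)
  sf_idx <- match(el$subfamily, subfams)
  for (mk in names(config$mark_probs)) {
    marks[[mk]] <- stats::rbinom(nrow(el), 1L, config$mark_probs[[mk]][sf_idx])
  }
  presence <- tibble::tibble(element_id = el$element_id)
  for (sp in names(config$species_splits)) {
    presence[[sp]] <- as.integer(el$age_mya > config$species_splits[[sp]])
  }

  structure(list(
    elements = el[, c("element_id", "chrom", "start", "end", "strand",
                      "structure", "sequence", "subfamily", "terminal_subs",
                      "age_mya")],
    founders = founders, founder_aln = founder_aln, ancestor = ancestor,
    backbone = backbone, blocks = blocks, blocks_aln = blocks_aln,
    events = events, marks = marks, presence = presence,
    config = config
  ), class = "ltr_truth")
}

#' @export
print.ltr_truth <- function(x, ...) {
  cat("Simulated LTR family:", nrow(x$elements), "elements,",
      x$config$n_subfamilies, "subfamilies,",
      nrow(x$events), "planted event(s)\n")
  invisible(x)
}

#' Write a simulated truth set to standard files
#'
#' Emits `elements.fasta`, `elements.bed`, `labels.tsv`, `events.tsv`,
#' `presence.tsv`, `ages.tsv` and one `marks/<mark>.bed` peak file per mark
#' (a peak exactly covering each positive element).
#'
#' @param truth An `ltr_truth` from [simulate_family()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_truth <- function(truth, outdir) {
  stopifnot(inherits(truth, "ltr_truth"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  el <- truth$elements
  write_fasta(stats::setNames(el$sequence, el$element_id),
              file.path(outdir, "elements.fasta"))
  write_bed(dplyr::transmute(el, .data$chrom, .data$start, .data$end,
                             name = .data$element_id, .data$strand),
            file.path(outdir, "elements.bed"))
  readr::write_tsv(el[, c("element_id", "subfamily")],
                   file.path(outdir, "labels.tsv"))
  readr::write_tsv(truth$events, file.path(outdir, "events.tsv"))
  readr::write_tsv(truth$presence, file.path(outdir, "presence.tsv"))
  readr::write_tsv(el[, c("element_id", "age_mya", "terminal_subs")],
                   file.path(outdir, "ages.tsv"))
  dir.create(file.path(outdir, "marks"), showWarnings = FALSE)
  for (mk in setdiff(names(truth$marks), "element_id")) {
    pos <- el[truth$marks[[mk]] == 1L, ]
    write_bed(dplyr::transmute(pos, .data$chrom, .data$start, .data$end,
                               name = paste0(mk, "_peak_", .data$element_id)),
              file.path(outdir, "marks", paste0(mk, ".bed")))
  }
  invisible(outdir)
}
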