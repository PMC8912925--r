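#' Pipeline configuration
#'
#' Central home for every tunable threshold of the analysis flow, with the
#' defaults used throughout: clade support 0.95, clade size > 10, subtending
#' branch > 0.015 subs/site, 51% consensus majority, LTR length > 350 bp,
#' full-length span > 4 kb, any-overlap peak calls, FPKM > 2 expression
#' calls, alpha 0.05, motif cutoff 1e-5.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param simulate Simulate the input family (default TRUE)?
#' @param sim A [sim_config()] (defaults to `sim_config(seed)`).
#' @param fasta,alignment,tree Optional input paths overriding simulation /
#'   built-in alignment / built-in tree building.
#' @param peaks Optional named character vector of peak BED paths (one per
#'   mark); defaults to the simulated marks.
#' @param support_min,size_min,branch_min Partition thresholds.
#' @param consensus_frac Majority-rule fraction.
#' @param min_nongap_frac Column filter threshold.
#' @param bootstrap_reps Bootstrap replicates for the family tree.
#' @param overlap_mode,min_bp,min_frac Peak-call mode and thresholds.
#' @param fpkm_threshold Expression call threshold.
#' @param alpha Significance level for enrichment summaries.
#' @param motif_cutoff Motif enrichment p cutoff.
#' @param n_blocks Number of equal consensus-alignment blocks for the
#'   recombination and motif stages.
#' @param pwms Optional list of [pwm()]s for the motif stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            sim = NULL, fasta = NULL, alignment = NULL,
                            tree = NULL, peaks = NULL,
                            support_min = 0.95, size_min = 10,
                            branch_min = 0.015, consensus_frac = 0.51,
                            min_nongap_frac = 0.01, bootstrap_reps = 100,
                            overlap_mode = "bp", min_bp = 1L,
                            min_frac = 0.7, fpkm_threshold = 2,
                            alpha = 0.05, motif_cutoff = 1e-5,
                            n_blocks = 7L, pwms = NULL) {
  stopifnot(support_min > 0, support_min <= 1, size_min >= 2,
            branch_min >= 0, consensus_frac > 0.5, consensus_frac <= 1,
            min_nongap_frac >= 0, min_nongap_frac <= 1,
            bootstrap_reps >= 1, overlap_mode %in% c("bp", "fraction"),
            alpha > 0, alpha < 1, motif_cutoff > 0, motif_cutoff < 1)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full phyloregulatory pipeline
#'
#' Executes simulate/load, align, filter, tree, partition, consensus,
#' network, dating, overlay, recombination and motif stages in order,
#' writing each stage's tables under `config$outdir` together with a run
#' manifest recording the seed and every threshold. Reruns with the same
#' configuration and seed reproduce the outputs.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; results are also returned as a
#'   list (`truth`, `alignment`, `tree`, `partition`, `consensuses`,
#'   `network`, `orthology`, `ages`, `calls`, `proportions`, `enrichment`,
#'   `incongruence`, `motifs`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  truth <- NULL
  if (config$simulate) {
    truth <- run_stage("simulate", {
      tr <- simulate_family(config$sim)
      write_truth(tr, file.path(outdir, "truth"))
      tr
    })
    seqs <- stats::setNames(truth$elements$sequence,
                            truth$elements$element_id)
    stage_log("simulate", length(seqs), " elements, ",
              config$sim$n_subfamilies, " subfamilies")
  } else {
    if (is.null(config$fasta) || !file.exists(config$fasta)) {
      stop("pipeline stage 'load' failed: input FASTA not found: ",
           config$fasta)
    }
    seqs <- read_fasta(config$fasta)
    stage_log("load", length(seqs), " sequences from ", config$fasta)
  }
  res$truth <- truth

  aln <- run_stage("align", {
    if (!is.null(config$alignment)) read_fasta(config$alignment)
    else align_to_reference(seqs)
  })
  stage_log("align", length(aln), " x ", nchar(aln[[1]]), " alignment")

  aln <- run_stage("filter", filter_columns(aln, config$min_nongap_frac))
  stage_log("filter", nchar(aln[[1]]), " columns kept")
  res$alignment <- aln

  fam_tree <- run_stage("tree", {
    if (!is.null(config$tree)) read_tree(config$tree)
    else bootstrap_support(aln, reps = config$bootstrap_reps,
                           seed = config$seed)
  })
  write_tree(fam_tree, file.path(outdir, "tree.nwk"))
  stage_log("tree", length(fam_tree$tip.label), " tips")
  res$tree <- fam_tree

  part <- run_stage("partition", partition_tree(
    fam_tree, support_min = config$support_min,
    size_min = config$size_min, branch_min = config$branch_min
  ))
  readr::write_tsv(part$assignments, file.path(outdir, "partition.tsv"))
  stage_log("partition", nrow(part$clades), " subfamilies")
  res$partition <- part

  cons <- run_stage("consensus", consensus_set(aln, part,
                                               frac = config$consensus_frac))
  cons_aligned <- consensus_set(aln, part, frac = config$consensus_frac,
                                aligned = TRUE)
  if (length(cons) > 0L) {
    write_fasta(cons, file.path(outdir, "consensus.fasta"))
  }
  stage_log("consensus", length(cons), " consensus sequences")
  res$consensuses <- cons

  res$network <- run_stage("network", {
    if (length(cons_aligned) >= 2L) {
      net <- tryCatch({
        sizes <- table(part$assignments$subfamily)
        build_mjn(snp_matrix(cons_aligned),
                  sizes = stats::setNames(as.numeric(sizes), names(sizes)))
      }, error = function(e) {
        stage_log("network", "skipped: ", conditionMessage(e))
        NULL
      })
      if (!is.null(net)) {
        network_to_file(net, file.path(outdir, "network.tsv"))
        stage_log("network", nrow(net$nodes), " nodes, ", nrow(net$edges),
                  " edges")
      }
      net
    } else {
      stage_log("network", "skipped: fewer than 2 consensuses")
      NULL
    }
  })

  res$orthology <- run_stage("dating", {
    orth <- NULL
    if (!is.null(truth)) {
      orth <- orthology_profile(
        truth$presence, part,
        species_order = names(sort(config$sim$species_splits))
      )
      readr::write_tsv(orth, file.path(outdir, "dating_orthology.tsv"))
    }
    orth
  })
  res$ages <- run_stage("dating", {
    if (nrow(part$clades) >= 2L) {
      grouping <- stats::setNames(part$clades$subfamily,
                                  part$clades$subfamily)
      ag <- age_groups(fam_tree, part, grouping)
      readr::write_tsv(ag$tests, file.path(outdir, "dating_tests.tsv"))
      stage_log("dating", ag$n_tests, " pairwise age tests")
      ag
    } else NULL
  })

  run_overlay <- !is.null(truth) || !is.null(config$peaks)
  if (run_overlay) {
    calls <- run_stage("overlay", {
      el <- if (!is.null(truth)) truth$elements else
        stop("overlay without simulation requires element intervals")
      peak_files <- config$peaks
      if (is.null(peak_files)) {
        mk <- setdiff(names(truth$marks), "element_id")
        peak_files <- stats::setNames(
          file.path(outdir, "truth", "marks", paste0(mk, ".bed")), mk
        )
      }
      missing <- peak_files[!file.exists(peak_files)]
      if (length(missing) > 0L) {
        stop("peak file(s) not found: ", paste(missing, collapse = ", "))
      }
      purrr::map_dfr(names(peak_files), function(mk) {
        call_peak_overlap(el, read_bed(peak_files[[mk]]), mark = mk,
                          mode = config$overlap_mode,
                          min_bp = config$min_bp,
                          min_frac = config$min_frac)
      })
    })
    readr::write_tsv(calls, file.path(outdir, "calls.tsv"))
    res$calls <- calls
    res$proportions <- subfamily_proportions(calls, part)
    readr::write_tsv(res$proportions, file.path(outdir, "proportions.tsv"))
    if (nrow(part$clades) >= 2L) {
      focal <- part$clades$subfamily[1]
      res$enrichment <- enrichment_tests(calls, part, focal_group = focal)
      readr::write_tsv(res$enrichment, file.path(outdir, "enrichment.tsv"))
      stage_log("overlay", nrow(res$enrichment), " enrichment tests vs ",
                focal)
    }
  }

  res$incongruence <- run_stage("recomb", {
    if (length(cons_aligned) >= 4L) {
      L <- nchar(cons_aligned[[1]])
      blocks <- sim_block_table(L, min(config$n_blocks, max(1L, L %/% 40L)))
      slices <- slice_blocks(cons_aligned, blocks)
      btr <- suppressWarnings(block_trees(slices, method = "nj",
                                          reps = config$bootstrap_reps,
                                          seed = config$seed))
      cons_tree <- tryCatch(
        bootstrap_support(cons_aligned, reps = config$bootstrap_reps,
                          seed = config$seed),
        error = function(e) NULL
      )
      if (is.null(cons_tree)) NULL else {
        ev <- detect_incongruence(btr, cons_tree,
                                  support_min = config$support_min)
        readr::write_tsv(ev, file.path(outdir, "events.tsv"))
        stage_log("recomb", nrow(ev), " incongruence event(s)")
        ev
      }
    } else {
      stage_log("recomb", "skipped: fewer than 4 consensuses")
      NULL
    }
  })

  res$motifs <- run_stage("motifs", {
    if (!is.null(config$pwms) && nrow(part$clades) >= 2L) {
      L <- nchar(aln[[1]])
      blocks <- sim_block_table(L, min(config$n_blocks, max(1L, L %/% 40L)))
      bs <- block_sequences(aln, part, blocks)
      me <- block_enrichment_all(bs, config$pwms,
                                 cutoff = config$motif_cutoff)
      readr::write_tsv(me, file.path(outdir, "motif_enrichment.tsv"))
      stage_log("motifs", nrow(me), " motif tests")
      me
    } else {
      stage_log("motifs", "skipped (no PWMs supplied)")
      NULL
    }
  })

  manifest <- c(
    package = as.character(utils::packageVersion("phyloreg")),
    seed = config$seed, simulate = config$simulate,
    support_min = config$support_min, size_min = config$size_min,
    branch_min = config$branch_min, consensus_frac = config$consensus_frac,
    min_nongap_frac = config$min_nongap_frac,
    bootstrap_reps = config$bootstrap_reps,
    overlap_mode = config$overlap_mode, min_bp = config$min_bp,
    min_frac = config$min_frac, fpkm_threshold = config$fpkm_threshold,
    alpha = config$alpha, motif_cutoff = config$motif_cutoff,
    n_blocks = config$n_blocks
  )
  writeLines(paste0(names(manifest), ": ", unname(manifest)),
             file.path(outdir, "manifest.txt"))
  res$outdir <- outdir
  invisible(res)
}
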