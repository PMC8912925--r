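#' Partition a supported phylogeny into subfamilies
#'
#' Implements the clade-calling rule used to split an LTR family into
#' subfamilies: an internal edge is a candidate when its bootstrap support is
#' at least `support_min`, its length exceeds `branch_min`
#' substitutions/site, and the smaller side of its bipartition holds strictly
#' more than `size_min` leaves. A subfamily is a *minimal* qualifying clade
#' (one containing no smaller qualifying clade): deeper backbone edges also
#' pass the edge test but subtend groups of subfamilies, and what separates
#' a single amplification burst from such a group is precisely that its own
#' supported internal branches stay short. Coarser qualifying clades are
#' kept in a diagnostics table. Leaves outside every accepted clade are
#' `"unassigned"`. The criterion is edge-based, so the result does not
#' depend on rooting or leaf order.
#'
#' @param tree An `ape::phylo` with numeric node supports in `[0, 1]`
#'   (see [bootstrap_support()] or [read_tree()]) and branch lengths.
#' @param support_min Minimum clade support (default 0.95).
#' @param size_min Clade size threshold; clades must exceed it strictly
#'   (default 10, i.e. at least 11 members).
#' @param branch_min Minimum subtending branch length in substitutions/site
#'   (default 0.015).
#' @return A `subfamily_partition` object: `assignments` (tibble
#'   `element_id`, `subfamily`), `clades` (per-subfamily support, branch
#'   length, size), `nested` (qualifying clades absorbed by a larger one)
#'   and the thresholds used.
#' @export
partition_tree <- function(tree, support_min = 0.95, size_min = 10,
                           branch_min = 0.015) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) {
    stop("tree has no support values; run bootstrap_support() first")
  }
  ntip <- length(tree$tip.label)
  all_taxa <- tree$tip.label
  splits <- tree_splits(tree)
  cand <- list()
  for (s in splits) {
    side <- s$tips
    other <- setdiff(all_taxa, side)
    small <- if (length(side) <= length(other)) side else other
    if (is.na(s$support) || s$support < support_min) next
    if (is.na(s$length) || s$length <= branch_min) next
    if (length(small) <= size_min) next
    cand[[length(cand) + 1L]] <- list(tips = small, support = s$support,
                                      length = s$length)
  }
  accepted <- list()
  nested <- list()
  if (length(cand) > 0L) {
    # dedup identical tip sets (zero-length edge chains)
    keys <- vapply(cand, function(x) paste(x$tips, collapse = "|"), "")
    cand <- cand[!duplicated(keys)]
    # minimality: drop candidates strictly containing another candidate
    # (backbone superclades); ties on identical tip sets keep one copy
    keep <- rep(TRUE, length(cand))
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i != j &&
            length(cand[[j]]$tips) < length(cand[[i]]$tips) &&
            all(cand[[j]]$tips %in% cand[[i]]$tips)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    accepted <- cand[keep]
    nested <- cand[!keep]
    ord <- order(-vapply(accepted, function(x) length(x$tips), 0L),
                 vapply(accepted, function(x) min(x$tips), ""))
    accepted <- accepted[ord]
  }
  assign <- stats::setNames(rep("unassigned", ntip), all_taxa)
  clades <- tibble::tibble(subfamily = character(), n_members = integer(),
                           support = numeric(), branch_length = numeric())
  for (i in seq_along(accepted)) {
    nm <- sprintf("S%d", i)
    assign[accepted[[i]]$tips] <- nm
    clades <- dplyr::add_row(clades, subfamily = nm,
                             n_members = length(accepted[[i]]$tips),
                             support = accepted[[i]]$support,
                             branch_length = accepted[[i]]$length)
  }
  nested_tbl <- tibble::tibble(
    members = vapply(nested, function(x) paste(x$tips, collapse = ","), ""),
    n_members = vapply(nested, function(x) length(x$tips), 0L),
    support = vapply(nested, function(x) x$support, 0),
    branch_length = vapply(nested, function(x) x$length, 0)
  )
  structure(list(
    assignments = tibble::tibble(element_id = all_taxa,
                                 subfamily = unname(assign)),
    clades = clades, nested = nested_tbl,
    support_min = support_min, size_min = size_min, branch_min = branch_min
  ), class = "subfamily_partition")
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat("Subfamily partition:", nrow(x$clades), "subfamilies,",
      sum(x$assignments$subfamily == "unassigned"), "unassigned of",
      nrow(x$assignments), "elements\n")
  print(x$clades)
  invisible(x)
}

#' @exportS3Method
tidy.subfamily_partition <- function(x, ...) x$assignments

#' @exportS3Method
glance.subfamily_partition <- function(x, ...) {
  tibble::tibble(
    n_elements = nrow(x$assignments),
    n_subfamilies = nrow(x$clades),
    n_unassigned = sum(x$assignments$subfamily == "unassigned"),
    min_support = if (nrow(x$clades)) min(x$clades$support) else NA_real_,
    support_min = x$support_min, size_min = x$size_min,
    branch_min = x$branch_min
  )
}

#' @exportS3Method
autoplot.subfamily_partition <- function(object, ...) {
  counts <- dplyr::count(object$assignments, .data$subfamily)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$subfamily,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subfamily", y = "members",
                  title = "Subfamily sizes") +
    ggplot2::theme_minimal()
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent symbol among `A,C,G,T,-` (frequency over
#' all rows; `N` never wins) is emitted if its frequency reaches `frac`;
#' a winning gap deletes the column; columns without a majority become `N`.
#'
#' @param aln Alignment (named character vector), e.g. one subfamily's rows.
#' @param frac Majority fraction (default 0.51; a 50/50 column yields `N`).
#' @return The consensus string over `A,C,G,T,N`; attribute `frame` gives
#'   the alignment columns each consensus position came from, attribute
#'   `aligned` the consensus in the full alignment frame (gaps retained).
#' @export
majority_consensus <- function(aln, frac = 0.51) {
  check_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  symbols <- c("A", "C", "G", "T", "-")
  aligned <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    cnt <- tabulate(factor(m[, j], levels = symbols), nbins = 5L)
    w <- which.max(cnt)
    aligned[j] <- if (cnt[w] / n >= frac) symbols[w] else "N"
  }
  frame <- which(aligned != "-")
  out <- paste(aligned[frame], collapse = "")
  attr(out, "frame") <- frame
  attr(out, "aligned") <- paste(aligned, collapse = "")
  out
}

#' Per-subfamily consensus sequences
#'
#' Applies [majority_consensus()] to each subfamily's alignment rows.
#'
#' @param aln Family alignment (named character vector keyed by element ID).
#' @param partition A `subfamily_partition` (or tibble with `element_id`,
#'   `subfamily`).
#' @param frac Majority fraction (default 0.51).
#' @param aligned Return consensuses in the shared alignment frame (gaps
#'   retained) rather than degapped? Default `FALSE`.
#' @return Named character vector of consensus sequences, one per subfamily
#'   (unassigned elements are skipped).
#' @export
consensus_set <- function(aln, partition, frac = 0.51, aligned = FALSE) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  asn <- asn[asn$subfamily != "unassigned" & asn$element_id %in% names(aln), ]
  sf <- sort(unique(asn$subfamily))
  out <- vapply(sf, function(s) {
    cons <- majority_consensus(aln[asn$element_id[asn$subfamily == s]], frac)
    if (aligned) attr(cons, "aligned") else as.character(cons)
  }, "")
  stats::setNames(out, sf)
}

#' Assign sequences to the nearest consensus
#'
#' Each sequence is globally aligned to every consensus and assigned to the
#' one with minimal p-distance (mismatches over aligned non-gap, non-N
#' columns); ties break by consensus name order.
#'
#' @param seqs Named character vector of sequences.
#' @param consensuses Named character vector of (degapped) consensus
#'   sequences.
#' @return Tibble `element_id`, `subfamily`, `distance`.
#' @export
assign_by_similarity <- function(seqs, consensuses) {
  stopifnot(length(consensuses) >= 1L, !is.null(names(consensuses)))
  cons_names <- sort(names(consensuses))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE
  )
  dist_to <- function(s, cons) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = s, subject = cons, type = "global",
      substitutionMatrix = submat, gapOpening = 4, gapExtension = 1
    )
    gp <- gapped_pairs(pa, s, cons)
    p <- strsplit(gp$pattern, "")[[1]]
    q <- strsplit(gp$subject, "")[[1]]
    ok <- p %in% c("A", "C", "G", "T") & q %in% c("A", "C", "G", "T")
    if (!any(ok)) return(1)
    sum(p[ok] != q[ok]) / sum(ok)
  }
  res <- purrr::map_dfr(names(seqs), function(id) {
    d <- vapply(cons_names, function(cn) dist_to(seqs[[id]],
                                                 consensuses[[cn]]), 0)
    best <- which.min(d) # which.min takes the first (name-order) tie
    tibble::tibble(element_id = id, subfamily = cons_names[best],
                   distance = unname(d[best]))
  })
  res
}

#' Terminal branch lengths per leaf
#'
#' @param tree An `ape::phylo`.
#' @return Named numeric vector: pendant edge length per tip.
#' @export
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[tip_edge], tree$tip.label)
}

#' Age-group comparison of terminal branch lengths
#'
#' Terminal branch lengths approximate post-insertion divergence and hence
#' element age. Subfamilies are mapped into groups (amplification waves) and
#' all pairwise groups are compared with two-sided Wilcoxon rank-sum tests
#' under Bonferroni correction (factor = number of pairwise tests).
#'
#' @param tree Tree whose tips are elements.
#' @param partition A `subfamily_partition` or assignments tibble.
#' @param grouping Named character vector mapping subfamily -> group name.
#' @return List of class `age_groups`: `per_element` tibble (`element_id`,
#'   `subfamily`, `group`, `terminal`), `summary` per group, `tests` tibble
#'   of pairwise Wilcoxon results with `padj`.
#' @export
age_groups <- function(tree, partition, grouping) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  tbl <- terminal_branch_lengths(tree)
  per <- asn %>%
    dplyr::filter(.data$element_id %in% names(tbl)) %>%
    dplyr::mutate(group = unname(grouping[.data$subfamily]),
                  terminal = unname(tbl[.data$element_id])) %>%
    dplyr::filter(!is.na(.data$group))
  if (dplyr::n_distinct(per$group) < 2L) {
    stop("grouping must map subfamilies to at least 2 groups")
  }
  summ <- per %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$terminal),
                     median = stats::median(.data$terminal), .groups = "drop")
  groups <- sort(unique(per$group))
  pairs <- utils::combn(groups, 2L)
  n_tests <- ncol(pairs)
  tests <- purrr::map_dfr(seq_len(n_tests), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    xa <- per$terminal[per$group == ga]
    xb <- per$terminal[per$group == gb]
    if (length(xa) < 2L || length(xb) < 2L) {
      return(tibble::tibble(group_a = ga, group_b = gb, statistic = NA_real_,
                            p = NA_real_, padj = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                              alternative = "two.sided"))
    tibble::tibble(group_a = ga, group_b = gb,
                   statistic = unname(wt$statistic), p = wt$p.value,
                   padj = pmin(1, wt$p.value * n_tests))
  })
  structure(list(per_element = per, summary = summ, tests = tests,
                 n_tests = n_tests), class = "age_groups")
}

#' @export
print.age_groups <- function(x, ...) {
  cat("Terminal-branch age comparison (", x$n_tests, " pairwise tests)\n",
      sep = "")
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' @exportS3Method
tidy.age_groups <- function(x, ...) x$tests

#' @exportS3Method
autoplot.age_groups <- function(object, ...) {
  ggplot2::ggplot(object$per_element,
                  ggplot2::aes(x = .data$group, y = .data$terminal)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "age group", y = "terminal branch length (subs/site)",
                  title = "Terminal branch lengths by amplification wave") +
    ggplot2::theme_minimal()
}

#' Orthologous presence profile per subfamily
#'
#' Fraction of each subfamily's members recovered as 1:1 orthologous
#' insertions in each species; species are ordered by the supplied
#' divergence order.
#'
#' @param presence Tibble with `element_id` plus one 0/1 column per species.
#' @param partition A `subfamily_partition` or assignments tibble.
#' @param species_order Optional character vector ordering the species
#'   columns (e.g. by divergence time).
#' @return Tibble `subfamily`, `species` (ordered factor), `n`, `shared`,
#'   `fraction`.
#' @export
orthology_profile <- function(presence, partition, species_order = NULL) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  asn <- asn[asn$subfamily != "unassigned", ]
  missing <- setdiff(asn$element_id, presence$element_id)
  if (length(missing) > 0L) {
    warning(length(missing), " element(s) missing from presence matrix; excluded")
    asn <- asn[!asn$element_id %in% missing, ]
  }
  species <- setdiff(names(presence), "element_id")
  if (is.null(species_order)) species_order <- species
  long <- presence %>%
    dplyr::inner_join(asn, by = "element_id") %>%
    tidyr::pivot_longer(dplyr::all_of(species), names_to = "species",
                        values_to = "present")
  out <- long %>%
    dplyr::group_by(.data$subfamily, .data$species) %>%
    dplyr::summarise(n = dplyr::n(), shared = sum(.data$present),
                     .groups = "drop") %>%
    dplyr::mutate(fraction = ifelse(.data$n > 0, .data$shared / .data$n, 0),
                  species = factor(.data$species, levels = species_order)) %>%
    dplyr::arrange(.data$subfamily, .data$species)
  out
}
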