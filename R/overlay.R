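#' Binary feature calls from peak overlap
#'
#' Intersects element intervals with (merged) peak intervals and calls an
#' element positive when the total overlap reaches `min_bp` base pairs
#' (`mode = "bp"`), or when the overlapped fraction of the element reaches
#' `min_frac` (`mode = "fraction"`, the stricter 70%-style rule). Overlap is
#' computed with interval trees ([GenomicRanges]), not all-pairs scanning.
#'
#' @param elements Tibble with `element_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param peaks Tibble with `chrom`, `start`, `end`.
#' @param mark Name of the mark being called.
#' @param mode `"bp"` (default) or `"fraction"`.
#' @param min_bp Minimum overlap in bp (default 1, i.e. any overlap).
#' @param min_frac Minimum overlapped fraction of the element (default 0.7).
#' @return Tibble `element_id`, `mark`, `call` (0/1), `overlap_bp`,
#'   `source`.
#' @export
call_peak_overlap <- function(elements, peaks, mark,
                              mode = c("bp", "fraction"),
                              min_bp = 1L, min_frac = 0.7) {
  mode <- match.arg(mode)
  el <- GenomicRanges::GRanges(
    elements$chrom,
    IRanges::IRanges(start = elements$start + 1L, end = elements$end)
  )
  ov_bp <- rep(0L, nrow(elements))
  if (nrow(peaks) > 0L) {
    pk <- GenomicRanges::reduce(GenomicRanges::GRanges(
      peaks$chrom,
      IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    ))
    hits <- GenomicRanges::findOverlaps(el, pk)
    if (length(hits) > 0L) {
      w <- IRanges::width(IRanges::pintersect(
        el[S4Vectors::queryHits(hits)], pk[S4Vectors::subjectHits(hits)]
      ))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov_bp[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  call <- if (mode == "bp") {
    as.integer(ov_bp >= min_bp)
  } else {
    as.integer(ov_bp / (elements$end - elements$start) >= min_frac)
  }
  tibble::tibble(element_id = elements$element_id, mark = mark,
                 call = call, overlap_bp = ov_bp, source = "peak_overlap")
}

#' Call the top septile of a signal
#'
#' Elements whose signal reaches the value of the `floor(n/7)`-th largest
#' observation are positive; boundary ties are all included. Used for
#' nascent-transcription signal whose visible activity concentrates in the
#' top seventh of elements.
#'
#' @param signal Named numeric vector (element -> signal) or tibble with
#'   `element_id` and `value`.
#' @param mark Mark name (default `"GRO-seq"`).
#' @return Tibble `element_id`, `mark`, `call`, `source`.
#' @export
call_top_septile <- function(signal, mark = "GRO-seq") {
  if (is.data.frame(signal)) {
    signal <- stats::setNames(signal$value, signal$element_id)
  }
  if (anyNA(signal)) {
    warning(sum(is.na(signal)), " missing signal value(s) treated as 0")
    signal[is.na(signal)] <- 0
  }
  n <- length(signal)
  stopifnot(n >= 7L)
  k <- max(1L, floor(n / 7))
  thr <- sort(signal, decreasing = TRUE)[k]
  call <- as.integer(signal >= thr)
  if (all(call == 1L)) {
    message("all signal values tie at the septile boundary; all called positive")
  }
  tibble::tibble(element_id = names(signal), mark = mark, call = call,
                 source = "septile")
}

#' Call highly expressed elements
#'
#' Positive iff expression strictly exceeds `threshold` (FPKM > 2 by
#' default).
#'
#' @param fpkm Named numeric vector (element -> FPKM) or tibble with
#'   `element_id` and `value`.
#' @param threshold Expression threshold (default 2).
#' @param mark Mark name (default `"RNA-seq"`).
#' @return Tibble `element_id`, `mark`, `call`, `source`.
#' @export
call_expression <- function(fpkm, threshold = 2, mark = "RNA-seq") {
  if (is.data.frame(fpkm)) fpkm <- stats::setNames(fpkm$value, fpkm$element_id)
  stopifnot(all(fpkm >= 0, na.rm = TRUE))
  tibble::tibble(element_id = names(fpkm), mark = mark,
                 call = as.integer(!is.na(fpkm) & fpkm > threshold),
                 source = "expression_threshold")
}

#' Per-subfamily proportions of positive calls
#'
#' @param calls Tibble of feature calls (`element_id`, `mark`, `call`),
#'   typically several call sets row-bound together.
#' @param partition A `subfamily_partition` or assignments tibble.
#' @return Tibble `subfamily`, `mark`, `n`, `positives`, `proportion`.
#'   Elements of a subfamily with no call row for a mark count as negative;
#'   unassigned elements are excluded.
#' @export
subfamily_proportions <- function(calls, partition) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  asn <- asn[asn$subfamily != "unassigned", ]
  marks <- unique(calls$mark)
  grid <- tidyr::expand_grid(asn, mark = marks)
  grid %>%
    dplyr::left_join(calls[, c("element_id", "mark", "call")],
                     by = c("element_id", "mark")) %>%
    dplyr::mutate(call = dplyr::coalesce(.data$call, 0L)) %>%
    dplyr::group_by(.data$subfamily, .data$mark) %>%
    dplyr::summarise(n = dplyr::n(), positives = sum(.data$call),
                     .groups = "drop") %>%
    dplyr::mutate(proportion = ifelse(.data$n > 0,
                                      .data$positives / .data$n, NA_real_))
}

#' Plot a subfamily-by-mark proportion heatmap
#'
#' @param proportions Output of [subfamily_proportions()].
#' @return A ggplot.
#' @export
plot_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$mark, y = .data$subfamily,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Proportion of elements positive per mark") +
    ggplot2::theme_minimal()
}

#' Subfamily enrichment tests for binary marks
#'
#' For every mark and every comparator subfamily, tests the 2x2 table
#' (positive/negative x focal/comparator) with a chi-square test without
#' continuity correction; tables with an expected cell below 1 fall back to
#' Fisher's exact test (flagged in `method`). P-values are
#' Bonferroni-adjusted by the total number of tests performed in the call.
#'
#' @param calls Tibble of feature calls (`element_id`, `mark`, `call`).
#' @param partition A `subfamily_partition` or assignments tibble.
#' @param focal_group Subfamily (or vector of subfamilies pooled) tested
#'   against each other subfamily.
#' @param marks Marks to test (default: all in `calls`).
#' @return Tibble sorted by `padj` with the 2x2 counts, `statistic`, `p`,
#'   `padj` and `n_tests`.
#' @export
enrichment_tests <- function(calls, partition, focal_group, marks = NULL) {
  asn <- if (inherits(partition, "subfamily_partition"))
    partition$assignments else dplyr::as_tibble(partition)
  asn <- asn[asn$subfamily != "unassigned", ]
  stopifnot(any(asn$subfamily %in% focal_group))
  if (is.null(marks)) marks <- unique(calls$mark)
  comparators <- sort(setdiff(unique(asn$subfamily), focal_group))
  stopifnot(length(comparators) >= 1L)

  counts_for <- function(ids, mark) {
    pos <- calls$element_id[calls$mark == mark & calls$call == 1L]
    c(pos = sum(ids %in% pos), neg = sum(!ids %in% pos))
  }
  focal_ids <- asn$element_id[asn$subfamily %in% focal_group]
  grid <- tidyr::expand_grid(mark = marks, group_b = comparators)
  n_tests <- nrow(grid)
  res <- purrr::map_dfr(seq_len(n_tests), function(i) {
    mk <- grid$mark[i]; gb <- grid$group_b[i]
    fa <- counts_for(focal_ids, mk)
    fb <- counts_for(asn$element_id[asn$subfamily == gb], mk)
    tab <- matrix(c(fa, fb), nrow = 2L, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      ft <- stats::fisher.test(tab)
      stat <- NA_real_; p <- ft$p.value; method <- "fisher"
    } else if (any(colSums(tab) == 0)) {
      stat <- 0; p <- 1; method <- "chisq"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value; method <- "chisq"
    }
    tibble::tibble(mark = mk, group_a = paste(focal_group, collapse = "+"),
                   group_b = gb, a_pos = fa[["pos"]], a_neg = fa[["neg"]],
                   b_pos = fb[["pos"]], b_neg = fb[["neg"]],
                   statistic = stat, p = p, method = method)
  })
  res %>%
    dplyr::mutate(n_tests = n_tests, padj = pmin(1, .data$p * n_tests)) %>%
    dplyr::arrange(.data$padj, .data$p)
}
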