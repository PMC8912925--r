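#' SNP matrix from aligned consensus sequences
#'
#' Retains exactly the alignment columns that are gap-free and `N`-free in
#' every taxon and polymorphic, the site set used for haplotype network
#' construction.
#'
#' @param aln Aligned consensus sequences (named character vector).
#' @return A `snp_matrix`: `taxa`, `sites` (original column indices),
#'   `states` (taxa x sites character matrix).
#' @export
snp_matrix <- function(aln) {
  m <- aln_matrix(aln)
  clean <- colSums(m == "-" | m == "N") == 0L
  poly <- apply(m, 2L, function(col) length(unique(col)) > 1L)
  keep <- which(clean & poly)
  if (length(keep) == 0L) stop("no gap-free polymorphic columns (no SNPs)")
  structure(list(taxa = rownames(m), sites = keep,
                 states = m[, keep, drop = FALSE]),
            class = "snp_matrix")
}

hamming <- function(states) {
  n <- nrow(states)
  d <- matrix(0L, n, n, dimnames = list(rownames(states), rownames(states)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- sum(states[i, ] != states[j, ])
    }
  }
  d
}

# minimax (bottleneck) closure of a distance matrix
minimax_closure <- function(d) {
  mm <- d
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      m <- pmax(mm[i, k], mm[k, ])
      upd <- m < mm[i, ]
      mm[i, upd] <- m[upd]
    }
  }
  mm
}

# minimum spanning network edges: all pairs whose direct distance does not
# exceed their minimax path distance + epsilon
msn_edges <- function(d, epsilon = 0) {
  mm <- minimax_closure(d)
  n <- nrow(d)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && d[i, j] <= mm[i, j] + epsilon) {
        out <- rbind(out, c(i, j, d[i, j]))
      }
    }
  }
  out
}

site_majority <- function(a, b, c) {
  vapply(seq_along(a), function(s) {
    x <- c(a[s], b[s], c[s])
    tab <- table(x)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else a[s]
  }, "")
}

#' Median-joining haplotype network
#'
#' Re-implementation of the median-joining algorithm of Bandelt et al.:
#' iteratively builds the minimum spanning network over the current node set
#' under Hamming distance, adds the per-site majority (median) vector of
#' connected node triples when novel, and on convergence prunes median
#' vectors that do not lie on any shortest path between observed taxa.
#' Deterministic: nodes are processed in sorted label order, and the
#' majority tie at a site (all three states distinct) resolves to the state
#' of the first node of the triple in that order.
#'
#' @param snp A [snp_matrix()].
#' @param epsilon Non-negative slack on the spanning-network threshold
#'   (default 0, the usual setting).
#' @param sizes Optional named numeric vector of member counts per taxon
#'   (stored as node attribute).
#' @param max_iter Maximum median-addition sweeps (default 25).
#' @return A `haplo_network`: `nodes` tibble (`label`, `type`, `size`),
#'   `edges` tibble (`from`, `to`, `weight` = Hamming distance), `states`
#'   matrix of all node vectors, `sites`.
#' @export
build_mjn <- function(snp, epsilon = 0, sizes = NULL, max_iter = 25L) {
  stopifnot(inherits(snp, "snp_matrix"), length(snp$taxa) >= 2L)
  states <- snp$states[order(rownames(snp$states)), , drop = FALSE]
  observed <- rownames(states)
  # collapse identical observed haplotypes into one node
  key <- apply(states, 1L, paste, collapse = "")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged_label <- vapply(key[first], function(k)
      paste(observed[key == k], collapse = "+"), "")
    states <- states[first, , drop = FALSE]
    rownames(states) <- merged_label
  }
  n_obs_nodes <- nrow(states)
  mv_count <- 0L
  for (iter in seq_len(max_iter)) {
    d <- hamming(states)
    ed <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, nrow(states), nrow(states))
    adj[ed[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    new_medians <- NULL
    nn <- nrow(states)
    for (i in seq_len(nn)) {
      for (j in seq_len(nn)) {
        for (k in seq_len(nn)) {
          if (i < j && j < k &&
              (adj[i, j] + adj[i, k] + adj[j, k]) >= 2L) {
            med <- site_majority(states[i, ], states[j, ], states[k, ])
            mkey <- paste(med, collapse = "")
            if (!(mkey %in% apply(states, 1L, paste, collapse = "")) &&
                !(mkey %in% if (is.null(new_medians)) character()
                  else apply(new_medians, 1L, paste, collapse = ""))) {
              new_medians <- rbind(new_medians, med)
            }
          }
        }
      }
    }
    if (is.null(new_medians)) break
    rownames(new_medians) <- sprintf("mv%d", mv_count + seq_len(nrow(new_medians)))
    mv_count <- mv_count + nrow(new_medians)
    states <- rbind(states, new_medians)
    if (iter == max_iter) {
      stop("median-joining did not converge in ", max_iter, " sweeps")
    }
  }

  # prune medians off every shortest observed-observed path, iteratively
  repeat {
    d <- hamming(states)
    ed <- msn_edges(d, epsilon)
    nn <- nrow(states)
    sp <- matrix(Inf, nn, nn); diag(sp) <- 0
    for (e in seq_len(nrow(ed))) {
      sp[ed[e, 1], ed[e, 2]] <- sp[ed[e, 2], ed[e, 1]] <- ed[e, 3]
    }
    for (k in seq_len(nn)) {
      for (i in seq_len(nn)) {
        m <- sp[i, k] + sp[k, ]
        upd <- m < sp[i, ]
        sp[i, upd] <- m[upd]
      }
    }
    is_med <- startsWith(rownames(states), "mv")
    obs_idx <- which(!is_med)
    useful <- rep(TRUE, nn)
    for (m in which(is_med)) {
      on_path <- FALSE
      for (a in obs_idx) {
        for (b in obs_idx) {
          if (a < b && sp[a, m] + sp[m, b] == sp[a, b]) {
            on_path <- TRUE
            break
          }
        }
        if (on_path) break
      }
      useful[m] <- on_path
    }
    if (all(useful)) break
    states <- states[useful, , drop = FALSE]
  }

  d <- hamming(states)
  ed <- msn_edges(d, epsilon)
  labels <- rownames(states)
  nodes <- tibble::tibble(
    label = labels,
    type = ifelse(startsWith(labels, "mv"), "median", "observed"),
    size = if (is.null(sizes)) NA_real_ else {
      vapply(labels, function(l) {
        parts <- strsplit(l, "+", fixed = TRUE)[[1]]
        if (all(parts %in% names(sizes))) sum(sizes[parts]) else NA_real_
      }, 0)
    }
  )
  edges <- tibble::tibble(from = labels[ed[, 1]], to = labels[ed[, 2]],
                          weight = as.integer(ed[, 3]))
  structure(list(nodes = nodes, edges = edges, states = states,
                 sites = snp$sites, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Median-joining network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "median"), "median ),", nrow(x$edges),
      "edges, total length", sum(x$edges$weight), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.haplo_network <- function(x, ...) x$edges

#' @exportS3Method
autoplot.haplo_network <- function(object, ...) {
  labels <- object$nodes$label
  nn <- length(labels)
  d <- matrix(Inf, nn, nn, dimnames = list(labels, labels)); diag(d) <- 0
  for (e in seq_len(nrow(object$edges))) {
    i <- match(object$edges$from[e], labels)
    j <- match(object$edges$to[e], labels)
    d[i, j] <- d[j, i] <- object$edges$weight[e]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) {
    m <- d[i, k] + d[k, ]; upd <- m < d[i, ]; d[i, upd] <- m[upd]
  }
  xy <- stats::cmdscale(d, k = 2)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  eg <- dplyr::mutate(object$edges,
                      x = xy[match(.data$from, labels), 1],
                      y = xy[match(.data$from, labels), 2],
                      xend = xy[match(.data$to, labels), 1],
                      yend = xy[match(.data$to, labels), 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = eg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type,
                                     size = ifelse(is.na(.data$size), 1,
                                                   .data$size))) +
    ggplot2::geom_text(data = nd[nd$type == "observed", ],
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::scale_size_continuous(name = "members") +
    ggplot2::labs(title = "Median-joining network") +
    ggplot2::theme_void()
}

#' Write / read a network edge list
#'
#' Writes the edge list as TSV (`from`, `to`, `weight`) and the node table
#' alongside it (suffix `_nodes.tsv`).
#'
#' @param net A `haplo_network`.
#' @param path Output TSV path for the edge list.
#' @return `path`, invisibly.
#' @export
network_to_file <- function(net, path) {
  stopifnot(inherits(net, "haplo_network"))
  readr::write_tsv(net$edges, path)
  readr::write_tsv(net$nodes, sub("(\\.tsv)?$", "_nodes.tsv", path))
  invisible(path)
}

#' @rdname network_to_file
#' @export
network_from_file <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  nodes_path <- sub("(\\.tsv)?$", "_nodes.tsv", path)
  nodes <- if (file.exists(nodes_path))
    readr::read_tsv(nodes_path, show_col_types = FALSE) else NULL
  list(nodes = nodes, edges = edges)
}
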