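# Evaluation against gold-standard networks and cross-cell-type network
# similarity / lineage recovery.

gold_standard_check <- function(gold) {
  if (!all(c("regulator", "target") %in% names(gold))) {
    stop("gold standard needs regulator and target columns")
  }
  if (!nrow(gold)) stop("gold standard is empty")
  if (any(gold$regulator == gold$target)) stop("gold standard contains self-edges")
  invisible(gold)
}

#' Restrict a network to the gold standard's universes
#'
#' Keeps edges whose regulator appears among the gold standard's regulators
#' and whose target appears among its targets.
#'
#' @param network Edge table (regulator, target, ...).
#' @param gold Gold-standard edge table.
#' @return The filtered network (warning when nothing remains).
#' @export
filter_to_gold <- function(network, gold) {
  gold_standard_check(gold)
  keep <- network$regulator %in% unique(gold$regulator) &
    network$target %in% unique(gold$target)
  out <- network[keep, , drop = FALSE]
  if (!nrow(out) && nrow(network)) {
    warning("no network edges remain after filtering to the gold standard")
  }
  rownames(out) <- NULL
  out
}

#' Area under the precision-recall curve
#'
#' Ranks edges by confidence (ties grouped at a common threshold), computes
#' precision/recall at every distinct threshold and integrates with
#' Davis-Goadrich interpolation: between successive threshold points the
#' true-positive count is stepped one unit at a time with false positives
#' interpolated linearly, and the area is accumulated by the trapezoid rule.
#' The segment from recall 0 to the first reachable recall uses the first
#' point's precision. Recall is relative to the total number of gold edges,
#' so positives never ranked cap the attainable recall.
#'
#' @param pred data.frame with regulator, target, confidence.
#' @param gold Gold-standard edge table (regulator, target).
#' @return AUPR in \[0,1\].
#' @export
aupr <- function(pred, gold) {
  gold_standard_check(gold)
  P <- nrow(unique(gold[, c("regulator", "target")]))
  if (!nrow(pred)) return(0)
  pos <- edge_key(pred$regulator, pred$target) %in%
    edge_key(gold$regulator, gold$target)
  ord <- order(-pred$confidence)
  pos <- pos[ord]
  confs <- pred$confidence[ord]
  # cumulative TP/FP at each distinct threshold
  block_end <- cumsum(rle(confs)$lengths)
  tp <- cumsum(pos)[block_end]
  fp <- block_end - tp
  # keep points where TP advances (plus the implicit origin 0,0)
  tp <- c(0, tp)
  fp <- c(0, fp)
  if (max(tp) == 0) return(0)
  area <- 0
  prev_r <- NA
  prev_p <- NA
  for (j in seq_len(length(tp) - 1L)) {
    ta <- tp[j]; fa <- fp[j]; tb <- tp[j + 1L]; fb <- fp[j + 1L]
    if (tb == ta) {
      # false positives only: recall unchanged, precision drops to this point
      if (ta > 0) {
        prev_r <- ta / P
        prev_p <- ta / (ta + fb)
      }
      next
    }
    for (x in seq(ta + 1L, tb)) {
      fx <- fa + (fb - fa) * (x - ta) / (tb - ta)
      r <- x / P
      p <- x / (x + fx)
      if (is.na(prev_r)) {
        area <- area + r * p  # flat extension from recall 0
      } else {
        area <- area + (r - prev_r) * (p + prev_p) / 2
      }
      prev_r <- r
      prev_p <- p
    }
  }
  area
}

#' F-score between two edge sets
#'
#' Harmonic mean of precision and recall of `predicted` against `reference`;
#' 0 when the sets are disjoint.
#'
#' @param predicted,reference Edge tables (regulator, target).
#' @return F-score in \[0,1\].
#' @export
fscore <- function(predicted, reference) {
  if (!nrow(predicted) || !nrow(reference)) return(0)
  kp <- unique(edge_key(predicted$regulator, predicted$target))
  kr <- unique(edge_key(reference$regulator, reference$target))
  tp <- length(intersect(kp, kr))
  if (tp == 0) return(0)
  p <- tp / length(kp)
  r <- tp / length(kr)
  2 * p * r / (p + r)
}

#' F-score of a cell type's top-k edges against a reference network
#'
#' @param conf An `edge_confidence` object.
#' @param cell_type Cell type column.
#' @param k Number of top edges.
#' @param reference Reference edge table.
#' @return F-score in \[0,1\].
#' @export
fscore_at_k <- function(conf, cell_type, k, reference) {
  fscore(top_k_edges(conf, cell_type, k), reference)
}

#' Predictable regulators by hypergeometric overlap
#'
#' For each regulator present in both the inferred network and the gold
#' standard, tests whether its predicted targets overlap its gold-standard
#' targets more than expected by chance (upper-tail hypergeometric test on
#' the shared gene universe). A regulator is called predictable when its
#' p-value is below `alpha`; no multiple-testing correction is applied.
#'
#' @param network Inferred edge table.
#' @param gold Gold-standard edge table.
#' @param alpha Significance cutoff (default 0.05).
#' @param universe Optional character vector of genes; defaults to the genes
#'   appearing in the inferred network (as regulator or target) that are also
#'   gold-standard targets.
#' @return data.frame per tested regulator: tf, n_predicted, n_gold, overlap,
#'   p_value, predictable.
#' @export
predictable_tfs <- function(network, gold, alpha = 0.05, universe = NULL) {
  gold_standard_check(gold)
  if (is.null(universe)) {
    universe <- intersect(unique(c(network$regulator, network$target)),
                          unique(gold$target))
  }
  N <- length(universe)
  tfs <- intersect(unique(network$regulator), unique(gold$regulator))
  rows <- lapply(tfs, function(tf) {
    predt <- intersect(unique(network$target[network$regulator == tf]), universe)
    goldt <- intersect(unique(gold$target[gold$regulator == tf]), universe)
    if (!length(predt)) return(NULL)  # nothing predicted inside the universe
    ov <- length(intersect(predt, goldt))
    p <- stats::phyper(ov - 1, length(goldt), N - length(goldt),
                       length(predt), lower.tail = FALSE)
    data.frame(tf = tf, n_predicted = length(predt), n_gold = length(goldt),
               overlap = ov, p_value = p, predictable = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), n_predicted = integer(),
                      n_gold = integer(), overlap = integer(),
                      p_value = numeric(), predictable = logical())
  }
  rownames(out) <- NULL
  out
}

#' Pairwise F-score similarity between cell type networks
#'
#' Symmetric matrix of F-scores between the top-k edge sets of every pair of
#' cell types; unit diagonal.
#'
#' @param conf An `edge_confidence` object.
#' @param k Number of top edges per cell type.
#' @return Cell-type x cell-type numeric matrix.
#' @export
pairwise_network_fscore <- function(conf, k) {
  types <- colnames(conf)
  tops <- lapply(stats::setNames(types, types), function(d) {
    suppressWarnings(top_k_edges(conf, d, k))
  })
  M <- diag(1, length(types))
  dimnames(M) <- list(types, types)
  if (length(types) > 1L) {
    for (i in seq_len(length(types) - 1L)) {
      for (j in seq(i + 1L, length(types))) {
        f <- fscore(tops[[i]], tops[[j]])
        M[i, j] <- M[j, i] <- f
      }
    }
  }
  M
}

#' Minimum spanning tree lineage from a distance matrix
#'
#' Builds the MST of a symmetric non-negative distance matrix (Prim's
#' algorithm; ties broken by edge name order) and roots it at the given
#' node, yielding a lineage tree. Useful with pseudobulk Euclidean distances
#' or `1 - pairwise_network_fscore()`.
#'
#' @param distances Symmetric numeric matrix with cell-type dimnames.
#' @param root Node to root the tree at.
#' @return A [lineage_tree()].
#' @export
mst_lineage <- function(distances, root) {
  nodes <- rownames(distances)
  if (is.null(nodes) || !root %in% nodes) stop("root must name a matrix row")
  if (any(distances < 0, na.rm = TRUE)) stop("distances must be non-negative")
  in_tree <- root
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  while (length(in_tree) < length(nodes)) {
    best <- NULL
    outside <- setdiff(nodes, in_tree)
    # candidate cut edges ordered by weight then alphabetical edge name
    for (a in sort(in_tree)) {
      for (b in sort(outside)) {
        w <- distances[a, b]
        if (!is.finite(w)) next
        if (is.null(best) || w < best$w) best <- list(a = a, b = b, w = w)
      }
    }
    if (is.null(best)) stop("distance matrix is disconnected (infinite distances)")
    parent[[best$b]] <- best$a
    in_tree <- c(in_tree, best$b)
  }
  lineage_tree(nodes, parent)
}

#' Pseudobulk Euclidean distances between cell types
#'
#' Distance matrix of the mean expression profiles of each cell type, the
#' standard input for MST-based lineage reconstruction from expression.
#'
#' @param exprs Named list of genes x cells matrices.
#' @return Symmetric distance matrix.
#' @export
pseudobulk_distances <- function(exprs) {
  prof <- t(vapply(exprs, rowMeans, numeric(nrow(exprs[[1L]]))))
  as.matrix(stats::dist(prof))
}
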