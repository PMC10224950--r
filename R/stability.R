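# Stability selection: repeated inference on cell subsamples, per-edge
# confidence scores, consensus networks.

#' Subsample cells of an expression matrix
#'
#' Draws `round(fraction * ncol)` columns uniformly without replacement,
#' keeping all genes and preserving the original column order. Deterministic
#' for a given seed.
#'
#' @param expr Genes x cells matrix.
#' @param fraction Fraction of cells to keep, in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled matrix.
#' @export
subsample_cells <- function(expr, fraction, seed) {
  validate_expression(expr)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0,1]")
  n <- ncol(expr)
  k <- round(fraction * n)
  if (k < 2) stop("subsample would have fewer than 2 cells")
  idx <- with_seed(seed, sort(sample.int(n, k)))
  expr[, idx, drop = FALSE]
}

#' Stability-selection edge confidences
#'
#' Runs the network inference on `n_subsamples` random cell subsamples of
#' every cell type and scores each edge by the fraction of subsample networks
#' that contain it. Subsample `i` uses seed `seed + i`.
#'
#' @param exprs Named list of expression matrices (one per tree node).
#' @param cfg An [inference_config()].
#' @param n_subsamples Number of subsamples (conventional settings: 20 for
#'   simulated data, 50 for real data).
#' @param fraction Fraction of cells per subsample (0.5 simulated, 2/3 real).
#' @param seed Integer seed.
#' @return An object of class `edge_confidence`: a numeric edges x cell-types
#'   matrix of confidences in \[0,1\] with `regulator`/`target` stored in
#'   `attr(, "edges")`; absent edges have confidence 0.
#' @export
grn_stability <- function(exprs, cfg, n_subsamples = 20, fraction = 0.5,
                          seed = 1) {
  if (n_subsamples < 1) stop("n_subsamples must be >= 1")
  types <- cfg$tree$nodes
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(n_subsamples)) {
    sub <- lapply(stats::setNames(types, types), function(d) {
      subsample_cells(exprs[[d]], fraction, derive_seed(seed, i))
    })
    res <- tryCatch(learn_networks(sub, cfg), error = function(e) {
      stop("inference failed on subsample ", i, ": ", conditionMessage(e))
    })
    for (d in types) {
      net <- res$networks[[d]]
      if (!nrow(net)) next
      keys <- edge_key(net$regulator, net$target)
      for (k in keys) {
        cur <- counts[[k]] %||% stats::setNames(numeric(length(types)), types)
        cur[[d]] <- cur[[d]] + 1
        counts[[k]] <- cur
      }
    }
  }
  keys <- sort(ls(counts))
  conf <- if (length(keys)) {
    t(vapply(keys, function(k) counts[[k]] / n_subsamples, numeric(length(types))))
  } else {
    matrix(numeric(), 0, length(types), dimnames = list(NULL, types))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  edge_confidence(conf, edges)
}

#' Construct an edge-confidence matrix object
#'
#' @param conf Numeric edges x cell-types matrix with values in \[0,1\].
#' @param edges data.frame with regulator and target columns, one row per
#'   row of `conf`.
#' @return An `edge_confidence` object.
#' @export
edge_confidence <- function(conf, edges) {
  if (nrow(conf) != nrow(edges)) stop("conf and edges disagree on edge count")
  if (length(conf) && (any(conf < 0) || any(conf > 1))) {
    stop("confidences must lie in [0,1]")
  }
  rownames(conf) <- edge_key(edges$regulator, edges$target)
  structure(conf, edges = edges, class = c("edge_confidence", "matrix"))
}

#' @export
print.edge_confidence <- function(x, ...) {
  cat("Edge confidence matrix:", nrow(x), "edges x", ncol(x), "cell types\n")
  if (nrow(x)) {
    cat("  mean nonzero confidence:", signif(mean(x[x > 0]), 3), "\n")
  }
  invisible(x)
}

#' Top-k edges of one cell type by confidence
#'
#' Ties are broken deterministically: confidence descending, then regulator,
#' then target name. Edges with zero confidence are never returned; if fewer
#' than `k` nonzero edges exist, all are returned with a warning.
#'
#' @param conf An `edge_confidence` object.
#' @param cell_type Column to rank.
#' @param k Number of edges.
#' @return data.frame with regulator, target, confidence.
#' @export
top_k_edges <- function(conf, cell_type, k) {
  if (k < 1) stop("k must be >= 1")
  edges <- attr(conf, "edges")
  v <- conf[, cell_type]
  keep <- v > 0
  edges <- edges[keep, , drop = FALSE]
  v <- v[keep]
  ord <- order(-v, edges$regulator, edges$target)
  if (k > length(v)) {
    warning("only ", length(v), " nonzero edges available for ", cell_type)
    k <- length(v)
  }
  sel <- ord[seq_len(k)]
  data.frame(regulator = edges$regulator[sel], target = edges$target[sel],
             confidence = unname(v[sel]), stringsAsFactors = FALSE)
}

#' Consensus network at a confidence threshold
#'
#' Returns, per cell type, the edges whose stability-selection confidence is
#' at least `threshold` (default 0.8, the "80% confidence network").
#'
#' @param conf An `edge_confidence` object.
#' @param threshold Minimum confidence.
#' @return Named list of edge tables (regulator, target, weight = confidence).
#' @export
consensus_networks <- function(conf, threshold = 0.8) {
  edges <- attr(conf, "edges")
  lapply(stats::setNames(colnames(conf), colnames(conf)), function(d) {
    keep <- conf[, d] >= threshold
    grn_edges(edges$regulator[keep], edges$target[keep],
              weight = unname(conf[keep, d]))
  })
}
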