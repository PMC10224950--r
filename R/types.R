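# Domain types: expression matrices, networks, lineage trees, prior configuration.

#' Validate a per-cell-type expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and cells
#' in columns; `rownames` are gene identifiers and `colnames` are cell
#' identifiers. Values are normalized expression units and must be finite.
#'
#' @param x A numeric matrix (genes x cells) with unique row names.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x))) stop("expression matrix must have gene row names")
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop("duplicate gene name in expression matrix: ", dup)
  }
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Construct a regulatory-network edge table
#'
#' A cell type's GRN is a data.frame with columns `regulator`, `target` and
#' `weight` (confidence or coefficient; defaults to 1). Self-edges are
#' disallowed.
#'
#' @param regulator,target Character vectors of equal length.
#' @param weight Numeric vector of edge weights (recycled).
#' @return A `data.frame` with columns regulator, target, weight.
#' @export
grn_edges <- function(regulator = character(), target = character(), weight = 1) {
  if (length(regulator) != length(target)) stop("regulator and target lengths differ")
  if (any(regulator == target)) stop("self-edges are not allowed")
  data.frame(
    regulator = as.character(regulator),
    target = as.character(target),
    weight = rep_len(as.numeric(weight), length(regulator)),
    stringsAsFactors = FALSE
  )
}

#' Construct a rooted cell lineage tree
#'
#' @param nodes Character vector of cell-type identifiers.
#' @param parent Named character vector mapping each non-root node to its
#'   parent; the root is the node absent from `names(parent)` (or mapped to
#'   `NA`).
#' @return An object of class `lineage_tree` with elements `nodes`, `parent`
#'   (named vector, `NA` for the root) and `root`.
#' @examples
#' lineage_tree(c("A", "B", "C"), c(B = "A", C = "B"))
#' @export
lineage_tree <- function(nodes, parent) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers in lineage tree")
  full <- rep(NA_character_, length(nodes))
  names(full) <- nodes
  if (length(parent)) {
    if (is.null(names(parent))) stop("parent must be a named vector")
    keep <- !is.na(parent)
    bad <- setdiff(names(parent), nodes)
    if (length(bad)) stop("parent map names unknown node: ", bad[1L])
    bad <- setdiff(parent[keep], nodes)
    if (length(bad)) stop("parent refers to unknown node: ", bad[1L])
    full[names(parent)] <- as.character(parent)
  }
  roots <- nodes[is.na(full)]
  if (length(roots) != 1L) {
    stop("lineage tree must have exactly one root, found ", length(roots))
  }
  tree <- structure(
    list(nodes = nodes, parent = full, root = roots),
    class = "lineage_tree"
  )
  # acyclicity + connectivity: walking up from every node must reach the root
  for (nd in nodes) {
    seen <- character()
    cur <- nd
    while (!is.na(tree$parent[[cur]])) {
      if (cur %in% seen) stop("cycle detected in lineage tree at node ", cur)
      seen <- c(seen, cur)
      cur <- tree$parent[[cur]]
    }
    if (cur != roots) stop("node ", nd, " does not reach the root")
  }
  tree
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("Lineage tree:", length(x$nodes), "cell types, root =", x$root, "\n")
  for (nd in tree_order(x)) {
    pa <- x$parent[[nd]]
    cat(" ", nd, if (is.na(pa)) "(root)" else paste0("<- ", pa), "\n")
  }
  invisible(x)
}

# children of a node
tree_children <- function(tree, node) {
  tree$nodes[!is.na(tree$parent) & tree$parent == node]
}

# nodes in root-to-leaf (breadth-first) order
tree_order <- function(tree) {
  out <- tree$root
  frontier <- tree$root
  while (length(frontier)) {
    nxt <- unlist(lapply(frontier, tree_children, tree = tree), use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Structure-prior configuration
#'
#' Bundles the parameters of the two structure priors: the logistic
#' cell-type-specific edge prior with sparsity penalty `beta0` (< 0) and
#' motif-prior strength `beta1` (>= 0), and the lineage edge-evolution chain
#' with root edge probability `p_root`, per-cell-type gain probability
#' `p_gain` and maintenance probability `p_maintain`.
#'
#' @param beta0 Negative real; penalty for adding an edge.
#' @param beta1 Non-negative real; strength of the motif-derived prior weight.
#' @param p_root Probability of an edge being present in the root cell type.
#' @param p_gain,p_maintain Probability of gaining an edge absent from the
#'   parent cell type / maintaining an edge present in the parent. Scalar, or
#'   a named vector with one entry per non-root cell type.
#' @param prior_weights Optional named list (by cell type) of data.frames with
#'   columns regulator, target, weight in (0,1]; missing pairs default to 0.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(beta0 = -0.9, beta1 = 0, p_root = 0.2,
                         p_gain = 0.2, p_maintain = 0.8,
                         prior_weights = NULL) {
  if (!is.numeric(beta0) || beta0 >= 0) stop("beta0 must be negative")
  if (!is.numeric(beta1) || beta1 < 0) stop("beta1 must be non-negative")
  stopifnot_scalar_prob(p_root, "p_root")
  stopifnot_scalar_prob(p_gain, "p_gain")
  stopifnot_scalar_prob(p_maintain, "p_maintain")
  lookup <- NULL
  if (!is.null(prior_weights)) {
    if (is.null(names(prior_weights))) stop("prior_weights must be named by cell type")
    lookup <- lapply(prior_weights, function(df) {
      if (!all(c("regulator", "target", "weight") %in% names(df))) {
        stop("prior_weights entries need regulator, target, weight columns")
      }
      w <- as.numeric(df$weight)
      if (any(w < 0 | w > 1)) stop("prior weights must lie in [0,1]")
      stats::setNames(w, edge_key(df$regulator, df$target))
    })
  }
  structure(
    list(beta0 = beta0, beta1 = beta1, p_root = p_root,
         p_gain = p_gain, p_maintain = p_maintain,
         prior_weights = prior_weights, .weight_lookup = lookup),
    class = "prior_config"
  )
}

# per-cell-type chain parameters (scalar or named vector)
chain_param <- function(value, d) {
  if (length(value) == 1L && is.null(names(value))) return(as.numeric(value))
  if (!d %in% names(value)) stop("no chain parameter for cell type ", d)
  as.numeric(value[[d]])
}

# prior weight m_uv^(d); 0 for unlisted pairs or cell types without a prior
prior_weight <- function(cfg, u, v, d) {
  lk <- cfg$.weight_lookup
  if (is.null(lk) || !d %in% names(lk)) return(rep(0, length(u)))
  w <- lk[[d]][edge_key(u, rep_len(v, length(u)))]
  w[is.na(w)] <- 0
  unname(w)
}
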