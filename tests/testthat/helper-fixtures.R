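# Shared builders and independent oracles for the test suite.

edge_keys <- function(net) paste(net$regulator, net$target, sep = "->")

# deterministic toy expression matrix
toy_expr <- function(genes, n_cells, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(length(genes) * n_cells), length(genes), n_cells,
              dimnames = list(genes, paste0("c", seq_len(n_cells))))
  x
}

# random small rooted tree over m nodes (node i's parent drawn among 1..i-1)
random_tree <- function(m, seed) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(m))
  parent <- character()
  if (m > 1) {
    for (i in 2:m) {
      parent[nodes[i]] <- nodes[sample.int(i - 1L, 1L)]
    }
  }
  lineage_tree(nodes, parent)
}

# brute-force chain log-probability (independent oracle for the incremental
# delta): direct product of root and branch factors
chain_logprob_oracle <- function(states, tree, cfg) {
  p_of <- function(d, s, pa_s) {
    p <- if (d == tree$root) cfg$p_root
    else if (pa_s == 1) mtgrn:::chain_param(cfg$p_maintain, d)
    else mtgrn:::chain_param(cfg$p_gain, d)
    if (s == 1) p else 1 - p
  }
  lp <- log(p_of(tree$root, states[[tree$root]], NA))
  for (d in setdiff(tree$nodes, tree$root)) {
    lp <- lp + log(p_of(d, states[[d]], states[[tree$parent[[d]]]]))
  }
  lp
}

# all 0/1 state vectors over the tree's nodes
all_state_vectors <- function(tree) {
  m <- length(tree$nodes)
  grid <- expand.grid(rep(list(0:1), m))
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.numeric(grid[i, ]), tree$nodes)
  })
}

# construct two vectors with an exact empirical correlation r (n cells)
vectors_with_cor <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  z <- residuals(lm(z ~ x))
  z <- z / sqrt(mean(z^2))
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}

# Independent oracle for aupr(): enumerate the full list of interpolated PR
# points (one per unit of true-positive count, with false positives linear
# between threshold points, and precision drops at false-positive-only
# thresholds), then integrate with the trapezoid rule, extending the first
# point's precision flat to recall zero.
aupr_oracle <- function(pred, gold) {
  ord <- order(-pred$confidence)
  pos <- paste(pred$regulator, pred$target) %in% paste(gold$regulator, gold$target)
  pos <- pos[ord]
  confs <- pred$confidence[ord]
  P <- nrow(gold)
  ends <- cumsum(rle(confs)$lengths)
  tp <- c(0, cumsum(pos)[ends])
  fp <- c(0, ends - cumsum(pos)[ends])
  rs <- ps <- numeric()
  for (j in seq_len(length(tp) - 1L)) {
    ta <- tp[j]; fa <- fp[j]; tb <- tp[j + 1L]; fb <- fp[j + 1L]
    if (tb == ta) {
      if (ta > 0) { rs <- c(rs, ta / P); ps <- c(ps, ta / (ta + fb)) }
      next
    }
    xs <- seq(ta + 1L, tb)
    fx <- fa + (fb - fa) * (xs - ta) / (tb - ta)
    rs <- c(rs, xs / P)
    ps <- c(ps, xs / (xs + fx))
  }
  if (!length(rs)) return(0)
  area <- rs[1] * ps[1]
  if (length(rs) > 1) {
    area <- area + sum(diff(rs) * (ps[-1] + ps[-length(ps)]) / 2)
  }
  area
}
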