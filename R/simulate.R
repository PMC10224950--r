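# Ground-truth lineage network simulation (probabilistic edge evolution on a
# lineage tree) and a linear-Gaussian synthetic expression generator with
# dropout-style sparsification.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark study conditions: a linear three-cell-type
#' lineage, 15 regulators among 65 genes, edge evolution with `p_root = 0.5`,
#' `p_gain = 0.4`, `p_maintain = 0.7`, 2000 cells per cell type, and 80%
#' dropout sparsity. `max_in_degree` (default 3) caps the number of
#' regulators per target by uniform down-sampling, bringing network sizes
#' into the benchmark's reported ~200-240 edge range.
#'
#' @param n_regulators Number of regulator genes (default 15).
#' @param n_genes Total number of genes including regulators (default 65).
#' @param tree A [lineage_tree()]; default is a linear 3-node chain
#'   C1 -> C2 -> C3.
#' @param p_root,p_gain,p_maintain Edge-evolution chain parameters (defaults
#'   0.5, 0.4, 0.7).
#' @param n_cells Cells per cell type (default 2000).
#' @param sparsity Fraction of expression entries set to zero (default 0.8).
#' @param max_in_degree Cap on regulators per target (`Inf` disables;
#'   default 3).
#' @param mean_shift Per-branch standard deviation of a random-walk shift in
#'   gene means along the lineage (default 0: all cell types mean-centred).
#'   Positive values separate pseudobulk profiles along the tree.
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_regulators = 15, n_genes = 65, tree = NULL,
                              p_root = 0.5, p_gain = 0.4, p_maintain = 0.7,
                              n_cells = 2000, sparsity = 0.8,
                              max_in_degree = 3, mean_shift = 0, seed = 1) {
  if (is.null(tree)) {
    tree <- lineage_tree(c("C1", "C2", "C3"), c(C2 = "C1", C3 = "C2"))
  }
  if (n_regulators > n_genes) stop("n_regulators cannot exceed n_genes")
  stopifnot_scalar_prob(sparsity, "sparsity", open = FALSE)
  structure(
    list(n_regulators = n_regulators, n_genes = n_genes, tree = tree,
         p_root = p_root, p_gain = p_gain, p_maintain = p_maintain,
         n_cells = n_cells, sparsity = sparsity,
         max_in_degree = max_in_degree, mean_shift = mean_shift, seed = seed),
    class = "simulation_config"
  )
}

# gene names: regulators R01.., targets share the pool G..
sim_gene_names <- function(cfg) {
  regs <- sprintf("R%02d", seq_len(cfg$n_regulators))
  tgts <- sprintf("G%02d", seq_len(cfg$n_genes - cfg$n_regulators))
  c(regs, tgts)
}

#' Simulate ground-truth networks by edge evolution on the lineage
#'
#' Candidate edges are all (regulator, target) pairs with target != regulator
#' (regulators may regulate each other). Each candidate's presence states
#' evolve as a two-state Markov chain over the tree: Bernoulli(`p_root`) at
#' the root; along each branch an edge present in the parent is kept with
#' `p_maintain` and an absent one gained with `p_gain`. If `max_in_degree`
#' is finite, targets with more regulators have excess in-edges removed
#' uniformly at random (applied per cell type after the chain).
#'
#' @param cfg A [simulation_config()].
#' @return Named list of edge tables, one per tree node.
#' @export
simulate_networks <- function(cfg) {
  genes <- sim_gene_names(cfg)
  regs <- genes[seq_len(cfg$n_regulators)]
  pairs <- expand.grid(regulator = regs, target = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  np <- nrow(pairs)
  ord <- tree_order(cfg$tree)
  with_seed(cfg$seed, {
    states <- matrix(0L, np, length(ord), dimnames = list(NULL, ord))
    states[, cfg$tree$root] <- as.integer(stats::runif(np) < cfg$p_root)
    for (d in setdiff(ord, cfg$tree$root)) {
      pa <- states[, cfg$tree$parent[[d]]]
      p <- ifelse(pa == 1L, chain_param(cfg$p_maintain, d),
                  chain_param(cfg$p_gain, d))
      states[, d] <- as.integer(stats::runif(np) < p)
    }
    lapply(stats::setNames(ord, ord), function(d) {
      keep <- states[, d] == 1L
      net <- pairs[keep, , drop = FALSE]
      if (is.finite(cfg$max_in_degree) && nrow(net)) {
        kept <- unlist(lapply(split(seq_len(nrow(net)), net$target), function(idx) {
          if (length(idx) <= cfg$max_in_degree) idx
          else sort(sample(idx, cfg$max_in_degree))
        }), use.names = FALSE)
        net <- net[sort(kept), , drop = FALSE]
      }
      grn_edges(net$regulator, net$target, weight = 1)
    })
  })
}

#' Simulate expression from a network (linear-Gaussian steady state)
#'
#' Assigns each edge a weight drawn as sign * Uniform(0.5, 1.5) with random
#' sign, rescales the weighted adjacency so its spectral radius is 0.8 (when
#' positive), and draws each cell as `x = (I - W')^{-1} e` with independent
#' standard-normal noise `e`. The conditional independence structure of the
#' resulting Gaussian matches the generating network, so ground-truth
#' recoverability is well defined. This is a deliberately simple stand-in
#' for nonlinear kinetic simulators of single-cell expression.
#'
#' @param grn Edge table (regulator, target).
#' @param genes Character vector: the full gene universe (row order of the
#'   output).
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed.
#' @param mean Optional named per-gene mean vector (default all zero).
#' @return Genes x cells numeric matrix.
#' @export
simulate_expression <- function(grn, genes, n_cells, seed, mean = NULL) {
  p <- length(genes)
  with_seed(seed, {
    W <- matrix(0, p, p, dimnames = list(genes, genes))
    if (nrow(grn)) {
      w <- stats::runif(nrow(grn), 0.5, 1.5) * sample(c(-1, 1), nrow(grn), TRUE)
      W[cbind(match(grn$regulator, genes), match(grn$target, genes))] <- w
    }
    for (attempt in seq_len(5L)) {
      rho <- max(Mod(eigen(W, only.values = TRUE)$values))
      if (rho > 0) W <- W * (0.8 / rho)
      A <- diag(p) - t(W)
      ok <- tryCatch({
        B <- solve(A)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      W <- W * 0.5
      if (attempt == 5L) stop("could not stabilise the network system")
    }
    eps <- matrix(stats::rnorm(p * n_cells), p, n_cells)
    x <- B %*% eps
    dimnames(x) <- list(genes, paste0("cell", seq_len(n_cells)))
    if (!is.null(mean)) x <- x + mean[genes]
    attr(x, "W") <- W  # realised edge weights, for diagnostics
    x
  })
}

#' Zero a fixed fraction of expression entries
#'
#' Mimics dropout by setting exactly `round(fraction * length(expr))` entries,
#' chosen uniformly without replacement over the whole matrix, to zero.
#'
#' @param expr Genes x cells matrix.
#' @param fraction Fraction of entries to zero, in \[0,1\].
#' @param seed Integer seed.
#' @return The sparsified matrix.
#' @export
sparsify <- function(expr, fraction, seed) {
  stopifnot_scalar_prob(fraction, "fraction", open = FALSE)
  k <- round(fraction * length(expr))
  if (k == 0) return(expr)
  idx <- with_seed(seed, sample.int(length(expr), k))
  expr[idx] <- 0
  expr
}

#' Simulate a full lineage dataset
#'
#' Convenience wrapper: evolves ground-truth networks on the lineage, draws
#' linear-Gaussian expression for each cell type (optionally with a
#' mean-shift random walk along the tree separating pseudobulk profiles) and
#' applies dropout sparsification.
#'
#' @param cfg A [simulation_config()].
#' @return List with `networks`, `expression` (sparsified), `clean`
#'   (pre-sparsification), `tree`, `regulators`, `genes` and `config`.
#' @export
simulate_lineage_data <- function(cfg = simulation_config()) {
  networks <- simulate_networks(cfg)
  genes <- sim_gene_names(cfg)
  ord <- tree_order(cfg$tree)
  means <- list()
  for (d in ord) {
    pa <- cfg$tree$parent[[d]]
    base <- if (is.na(pa)) rep(0, length(genes)) else means[[pa]]
    shift <- if (cfg$mean_shift > 0) {
      with_seed(derive_seed(cfg$seed, 7000 + match(d, ord)),
                stats::rnorm(length(genes), 0, cfg$mean_shift))
    } else {
      rep(0, length(genes))
    }
    means[[d]] <- stats::setNames(base + shift, genes)
  }
  clean <- lapply(stats::setNames(ord, ord), function(d) {
    simulate_expression(networks[[d]], genes, cfg$n_cells,
                        derive_seed(cfg$seed, 1000 + match(d, ord)),
                        mean = means[[d]])
  })
  expression <- lapply(stats::setNames(ord, ord), function(d) {
    sparsify(clean[[d]], cfg$sparsity, derive_seed(cfg$seed, 2000 + match(d, ord)))
  })
  list(networks = networks, expression = expression, clean = clean,
       tree = cfg$tree, regulators = genes[seq_len(cfg$n_regulators)],
       genes = genes, config = cfg)
}
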