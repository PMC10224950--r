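# Greedy score-based multi-task structure search over the lineage tree, and
# the single-task ablation that drops the lineage coupling.

#' Inference configuration
#'
#' @param regulators Character vector of candidate regulator gene names.
#' @param tree A [lineage_tree()] over the cell types.
#' @param prior A [prior_config()].
#' @param mode `"multitask"` couples cell types through the lineage
#'   edge-evolution chain; `"independent"` scores each cell type on data
#'   likelihood plus the logistic edge prior only.
#' @param max_regulators Cap on regulators per target gene (default
#'   unlimited).
#' @param max_rounds Maximum coordinate-ascent rounds per gene (default 10).
#' @param standardize Z-score each gene within each cell type before fitting
#'   (default TRUE).
#' @param var_floor Residual-variance floor (default 1e-6).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(regulators, tree, prior = prior_config(),
                             mode = c("multitask", "independent"),
                             max_regulators = Inf, max_rounds = 10,
                             standardize = TRUE, var_floor = 1e-6) {
  mode <- match.arg(mode)
  regulators <- as.character(regulators)
  if (!length(regulators)) stop("regulator list must be non-empty")
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  structure(
    list(regulators = regulators, tree = tree, prior = prior, mode = mode,
         max_regulators = max_regulators, max_rounds = max_rounds,
         standardize = standardize, var_floor = var_floor),
    class = "inference_config"
  )
}

#' Score one candidate regulator addition
#'
#' The change in the (log) posterior score from adding the edge
#' `candidate -> target` to cell type `cell_type`'s network: the gain in log
#' pseudo-likelihood of the target's conditional Gaussian, plus the change in
#' the structure log-prior. In multitask mode the prior change is the full
#' incremental structure prior (logistic term plus lineage chain conditioned
#' on the edge's current states in the other cell types); in independent mode
#' it is the logistic term's log-odds only.
#'
#' No standardization is applied here; pass the matrix on the scale you wish
#' to score (the fitting front end standardizes internally).
#'
#' @param expr_d Expression matrix of cell type `cell_type`.
#' @param target Target gene.
#' @param candidate Candidate regulator (must not equal `target` nor already
#'   regulate it).
#' @param current_grns Named list of edge tables, one per cell type, giving
#'   the current networks (used for the lineage chain states).
#' @param cfg An [inference_config()].
#' @param cell_type Cell type identifier for `expr_d`.
#' @return The score change (a real number).
#' @export
score_candidate <- function(expr_d, target, candidate, current_grns, cfg,
                            cell_type) {
  if (candidate == target) stop("candidate regulator equals the target")
  cur <- current_grns[[cell_type]]
  cur_regs <- if (!is.null(cur) && nrow(cur)) cur$regulator[cur$target == target] else character()
  if (candidate %in% cur_regs) stop("candidate already regulates the target")
  f0 <- fit_conditional_gaussian(expr_d, target, cur_regs, var_floor = cfg$var_floor)
  f1 <- fit_conditional_gaussian(expr_d, target, c(cur_regs, candidate),
                                 var_floor = cfg$var_floor)
  dlik <- cond_gaussian_loglik(f1, expr_d) - cond_gaussian_loglik(f0, expr_d)
  if (cfg$mode == "independent") {
    return(dlik + edge_prior_logodds(candidate, target, cell_type, cfg$prior))
  }
  states <- vapply(cfg$tree$nodes, function(d) {
    grn <- current_grns[[d]]
    as.numeric(!is.null(grn) && nrow(grn) &&
                 any(grn$regulator == candidate & grn$target == target))
  }, numeric(1))
  dlik + delta_structure_logprior(candidate, target, cell_type, 1,
                                  states, cfg$tree, cfg$prior)
}

# --- fast internal scoring on covariance matrices ---------------------------

# residual variance of target given regulator set, from a covariance matrix
cov_resvar <- function(C, g, S, floor) {
  if (!length(S)) return(max(C[g, g], floor))
  css <- C[S, S, drop = FALSE]
  cst <- C[S, g]
  sol <- tryCatch(solve(css, cst),
                  error = function(e) solve(css + diag(1e-8, length(S)), cst))
  max(C[g, g] - drop(crossprod(cst, sol)), floor)
}

# vectorised likelihood gain of adding each candidate to set S for target g
cov_lik_gains <- function(C, n, g, S, cands, s2_cur, floor) {
  if (!length(cands)) return(numeric())
  if (!length(S)) {
    r <- C[cands, g]
    q <- diag(C)[cands]
  } else {
    css <- C[S, S, drop = FALSE]
    csg <- C[S, g]
    csc <- C[cands, S, drop = FALSE]
    sol_g <- tryCatch(solve(css, csg),
                      error = function(e) solve(css + diag(1e-8, length(S)), csg))
    sol_c <- tryCatch(t(solve(css, t(csc))),
                      error = function(e) t(solve(css + diag(1e-8, length(S)), t(csc))))
    r <- C[cands, g] - drop(csc %*% sol_g)
    q <- diag(C)[cands] - rowSums(sol_c * csc)
  }
  s2_new <- s2_cur - ifelse(q > 1e-12, r^2 / pmax(q, 1e-12), 0)
  s2_new <- pmax(s2_new, floor)
  (n / 2) * (log(s2_cur) - log(s2_new))
}

# vectorised structure-prior change of switching each candidate edge ON in d,
# given the per-candidate state matrix across cell types
prior_deltas_on <- function(cands, target, d, states, cfg) {
  pr <- cfg$prior
  lo <- pr$beta0 + pr$beta1 * prior_weight(pr, cands, target, d)
  if (cfg$mode == "independent") return(lo)
  tree <- cfg$tree
  delta <- lo
  if (d == tree$root) {
    delta <- delta + log(pr$p_root) - log(1 - pr$p_root)
  } else {
    s_pa <- states[cands, tree$parent[[d]]]
    pm <- chain_param(pr$p_maintain, d)
    pg <- chain_param(pr$p_gain, d)
    p <- ifelse(s_pa == 1, pm, pg)
    delta <- delta + log(p) - log(1 - p)
  }
  for (ch in tree_children(tree, d)) {
    s_ch <- states[cands, ch]
    pm <- chain_param(pr$p_maintain, ch)
    pg <- chain_param(pr$p_gain, ch)
    delta <- delta + ifelse(s_ch == 1, log(pm / pg), log((1 - pm) / (1 - pg)))
  }
  delta
}

#' Learn one network per cell type
#'
#' Greedy coordinate-ascent structure search. For each target gene, rounds
#' proceed over cell types in root-to-leaf order; in each round every cell
#' type may add the single best-scoring regulator (if its score change is
#' positive), with the lineage chain conditioned on the edge's current states
#' in the other cell types. The search stops for a gene when a full round
#' adds nothing or `max_rounds` is reached. Ties are broken lexicographically
#' by regulator name. Target genes are mutually independent: the lineage
#' prior couples cell types per edge, never across targets, so results are
#' invariant to batching genes.
#'
#' @param exprs Named list of expression matrices, one per tree node.
#' @param cfg An [inference_config()].
#' @param targets Target genes to learn regulators for (default: every gene);
#'   batching targets across calls yields identical per-gene results.
#' @return List with `networks` (named list of edge tables), `trace`
#'   (data.frame of accepted moves with scores) and `score_total` (sum of
#'   accepted score changes; non-decreasing by construction).
#' @export
learn_networks <- function(exprs, cfg, targets = NULL) {
  tree <- cfg$tree
  if (!all(tree$nodes %in% names(exprs))) {
    stop("expression data missing for some cell types in the tree")
  }
  exprs <- exprs[tree$nodes]
  genes <- rownames(exprs[[1L]])
  for (d in tree$nodes) {
    validate_expression(exprs[[d]])
    if (!identical(sort(rownames(exprs[[d]])), sort(genes))) {
      stop("gene universe mismatch across cell types")
    }
  }
  regulators <- sort(cfg$regulators)
  missing <- setdiff(regulators, genes)
  if (length(missing)) stop("regulator absent from expression matrices: ", missing[1L])

  ord <- tree_order(tree)
  n_cells <- vapply(exprs, ncol, integer(1))
  Cs <- lapply(exprs, function(x) {
    x <- x[genes, , drop = FALSE]
    if (cfg$standardize) x <- standardize_rows(x)
    else x <- x - rowMeans(x)
    tcrossprod(x) / ncol(x)
  })

  targets <- targets %||% genes
  bad <- setdiff(targets, genes)
  if (length(bad)) stop("unknown target gene: ", bad[1L])

  edges <- lapply(stats::setNames(tree$nodes, tree$nodes),
                  function(d) list(reg = character(), tgt = character()))
  trace <- list()
  score_total <- 0

  for (g in targets) {
    cand_all <- setdiff(regulators, g)
    if (!length(cand_all)) next
    states <- matrix(0, length(cand_all), length(tree$nodes),
                     dimnames = list(cand_all, tree$nodes))
    S <- lapply(stats::setNames(ord, ord), function(d) character())
    s2 <- lapply(stats::setNames(ord, ord), function(d)
      max(Cs[[d]][g, g], cfg$var_floor))
    for (round in seq_len(cfg$max_rounds)) {
      added <- FALSE
      for (d in ord) {
        if (length(S[[d]]) >= cfg$max_regulators) next
        cands <- setdiff(cand_all, S[[d]])
        if (!length(cands)) next
        gains <- cov_lik_gains(Cs[[d]], n_cells[[d]], g, S[[d]], cands,
                               s2[[d]], cfg$var_floor)
        score <- gains + prior_deltas_on(cands, g, d, states, cfg)
        best <- which.max(score)  # cands sorted: first max = lexicographic tie-break
        if (score[best] > 0) {
          u <- cands[best]
          S[[d]] <- c(S[[d]], u)
          s2[[d]] <- cov_resvar(Cs[[d]], g, S[[d]], cfg$var_floor)
          states[u, d] <- 1
          edges[[d]]$reg <- c(edges[[d]]$reg, u)
          edges[[d]]$tgt <- c(edges[[d]]$tgt, g)
          score_total <- score_total + score[best]
          trace[[length(trace) + 1L]] <- data.frame(
            gene = g, cell_type = d, regulator = u, round = round,
            score = score[best], stringsAsFactors = FALSE)
          added <- TRUE
        }
      }
      if (!added) break
    }
  }

  networks <- lapply(edges, function(e) grn_edges(e$reg, e$tgt, weight = 1))
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(gene = character(), cell_type = character(),
               regulator = character(), round = integer(), score = numeric())
  list(networks = networks, trace = trace, score_total = score_total)
}

# z-score rows with maximum-likelihood sd; constant rows are left centred at 0
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  x <- x - mu
  s <- sqrt(rowMeans(x^2))
  s[s < 1e-12] <- 1
  x / s
}
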