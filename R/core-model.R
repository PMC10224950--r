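# Probabilistic scoring machinery: conditional-Gaussian pseudo-likelihood and
# the two structure priors (logistic edge prior + lineage edge-evolution chain).

#' Fit the conditional Gaussian for one target gene
#'
#' Models a target gene's expression as a Gaussian whose mean is a linear
#' function of its regulators' expression. Coefficients are the
#' ordinary-least-squares solution; the residual variance is the
#' maximum-likelihood estimate (denominator n), floored at `var_floor` so a
#' perfect fit never yields a degenerate density. With an empty regulator set
#' the marginal mean/variance are returned. Singular normal equations are
#' resolved deterministically by adding a ridge jitter of 1e-8 to the Gram
#' matrix.
#'
#' @param expr Numeric genes x cells matrix with gene row names.
#' @param target Target gene name (a row of `expr`).
#' @param regulators Character vector of regulator gene names (rows of
#'   `expr`); may be empty.
#' @param var_floor Lower bound for the residual variance (default 1e-6).
#' @return An object of class `cond_gaussian` with elements `target`,
#'   `regulators`, `coefficients` (named, per regulator), `intercept`,
#'   `residual_variance` and `n`.
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
#' fit_conditional_gaussian(x, "b", "a")
#' @export
fit_conditional_gaussian <- function(expr, target, regulators = character(),
                                     var_floor = 1e-6) {
  validate_expression(expr)
  regulators <- as.character(regulators)
  missing <- setdiff(c(target, regulators), rownames(expr))
  if (length(missing)) stop("gene not in expression matrix: ", missing[1L])
  n <- ncol(expr)
  if (length(regulators) >= n) stop("need |regulators| < number of cells")
  y <- expr[target, ]
  if (length(regulators) == 0L) {
    mu <- mean(y)
    s2 <- max(mean((y - mu)^2), var_floor)
    return(structure(
      list(target = target, regulators = character(), coefficients = numeric(),
           intercept = mu, residual_variance = s2, n = n),
      class = "cond_gaussian"
    ))
  }
  X <- cbind(1, t(expr[regulators, , drop = FALSE]))
  G <- crossprod(X)
  b <- tryCatch(
    solve(G, crossprod(X, y)),
    error = function(e) solve(G + diag(1e-8, nrow(G)), crossprod(X, y))
  )
  fitted <- drop(X %*% b)
  s2 <- max(mean((y - fitted)^2), var_floor)
  structure(
    list(target = target, regulators = regulators,
         coefficients = stats::setNames(unname(drop(b))[-1L], regulators),
         intercept = unname(drop(b))[1L], residual_variance = s2, n = n),
    class = "cond_gaussian"
  )
}

#' @export
print.cond_gaussian <- function(x, ...) {
  cat("Conditional Gaussian for", x$target, "|",
      if (length(x$regulators)) paste(x$regulators, collapse = ", ") else "(marginal)",
      "\n  residual variance:", signif(x$residual_variance, 4), "\n")
  invisible(x)
}

# Gaussian log-likelihood of the data under a fitted conditional
cond_gaussian_loglik <- function(fit, expr) {
  y <- expr[fit$target, ]
  mu <- fit$intercept
  if (length(fit$regulators)) {
    mu <- mu + drop(fit$coefficients %*% expr[fit$regulators, , drop = FALSE])
  }
  sum(stats::dnorm(y, mu, sqrt(fit$residual_variance), log = TRUE))
}

#' Log pseudo-likelihood of one cell type's network
#'
#' The pseudo-likelihood of a dependency network is the product over genes of
#' the conditional Gaussian density of each gene given its regulators in the
#' network. Returns its logarithm, summing over all genes (rows of `expr`)
#' and all cells.
#'
#' @param expr Numeric genes x cells matrix.
#' @param grn Edge table (data.frame with regulator, target columns) for this
#'   cell type; genes absent from `target` are modeled marginally.
#' @param var_floor Residual-variance floor passed to the per-gene fits.
#' @return A single real number, the log pseudo-likelihood.
#' @export
log_pseudo_likelihood <- function(expr, grn, var_floor = 1e-6) {
  validate_expression(expr)
  total <- 0
  for (g in rownames(expr)) {
    regs <- if (nrow(grn)) grn$regulator[grn$target == g] else character()
    fit <- fit_conditional_gaussian(expr, g, regs, var_floor = var_floor)
    total <- total + cond_gaussian_loglik(fit, expr)
  }
  total
}

#' Logistic edge prior probability
#'
#' Prior probability that the edge regulator `u` -> target `v` is present in
#' cell type `d`: `1 / (1 + exp(-(beta0 + beta1 * m_uv)))`, where `m_uv` is
#' the accessibility/motif-derived prior weight for the pair in that cell
#' type (0 when no prior is supplied). `beta0 < 0` penalises edges; `beta1 >=
#' 0` scales how strongly the prior weight promotes them.
#'
#' @param u,v Regulator and target gene names (u may be a vector).
#' @param d Cell type identifier.
#' @param cfg A [prior_config()].
#' @return Probability strictly in (0,1) (vectorised over `u`).
#' @export
edge_prior_prob <- function(u, v, d, cfg) {
  m <- prior_weight(cfg, u, v, d)
  stats::plogis(cfg$beta0 + cfg$beta1 * m)
}

# log-odds form of the logistic prior: log P(I=1) - log P(I=0)
edge_prior_logodds <- function(u, v, d, cfg) {
  cfg$beta0 + cfg$beta1 * prior_weight(cfg, u, v, d)
}

#' Log-probability of one edge's presence states along the lineage
#'
#' The lineage structure prior treats each candidate edge independently as a
#' two-state Markov chain over the lineage tree: present at the root with
#' probability `p_root`; along each branch, an edge present in the parent is
#' maintained with probability `p_maintain` and an edge absent from the
#' parent is gained with probability `p_gain`.
#'
#' @param states Named 0/1 vector of edge states, one entry per tree node.
#' @param tree A [lineage_tree()].
#' @param cfg A [prior_config()].
#' @return The log-probability of the state vector under the chain.
#' @examples
#' tr <- lineage_tree(c("A", "B", "C"), c(B = "A", C = "B"))
#' cfg <- prior_config(p_root = 0.5, p_maintain = 0.8)
#' lineage_edge_chain_logprob(c(A = 1, B = 1, C = 1), tr, cfg)  # log 0.32
#' @export
lineage_edge_chain_logprob <- function(states, tree, cfg) {
  missing <- setdiff(tree$nodes, names(states))
  if (length(missing)) stop("missing edge state for node ", missing[1L])
  lp <- node_chain_logfactor(tree$root, states[[tree$root]], NA, tree$root, cfg)
  for (d in setdiff(tree$nodes, tree$root)) {
    pa <- tree$parent[[d]]
    lp <- lp + node_chain_logfactor(d, states[[d]], states[[pa]], tree$root, cfg)
  }
  lp
}

# log of the chain factor contributed by node d given its own state and its
# parent's state (parent_state = NA for the root)
node_chain_logfactor <- function(d, state, parent_state, root, cfg) {
  if (d == root) {
    p <- cfg$p_root
  } else if (parent_state == 1) {
    p <- chain_param(cfg$p_maintain, d)
  } else {
    p <- chain_param(cfg$p_gain, d)
  }
  log(if (state == 1) p else 1 - p)
}

#' Change in the structure log-prior when one edge flips in one cell type
#'
#' The full structure prior is the product of the cell-type-specific logistic
#' edge prior and the lineage edge-evolution chain. Flipping the state of
#' edge (u, v) in cell type `d` only changes the logistic term of `d`, the
#' chain factor of `d` itself (root factor or parent link) and the chain
#' factors of `d`'s children. This computes the resulting change in
#' log-prior incrementally.
#'
#' @param u,v Regulator and target gene names.
#' @param d Cell type in which the edge state flips.
#' @param flip_to New state, 0 or 1 (the current state must be `1 - flip_to`).
#' @param current_states Named 0/1 vector of the edge's current state in every
#'   cell type.
#' @param tree A [lineage_tree()].
#' @param cfg A [prior_config()].
#' @return The change in `log P(structure)`.
#' @export
delta_structure_logprior <- function(u, v, d, flip_to, current_states, tree, cfg) {
  missing <- setdiff(tree$nodes, names(current_states))
  if (length(missing)) stop("missing edge state for node ", missing[1L])
  old <- current_states[[d]]
  if (old == flip_to) return(0)
  # logistic (cell-type-specific) part: log-odds with the appropriate sign
  lo <- edge_prior_logodds(u, v, d, cfg)
  delta <- if (flip_to == 1) lo else -lo
  # chain part: d's own factor
  pa_state <- if (d == tree$root) NA else current_states[[tree$parent[[d]]]]
  delta <- delta +
    node_chain_logfactor(d, flip_to, pa_state, tree$root, cfg) -
    node_chain_logfactor(d, old, pa_state, tree$root, cfg)
  # chain part: links to d's children
  for (ch in tree_children(tree, d)) {
    delta <- delta +
      node_chain_logfactor(ch, current_states[[ch]], flip_to, tree$root, cfg) -
      node_chain_logfactor(ch, current_states[[ch]], old, tree$root, cfg)
  }
  delta
}
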