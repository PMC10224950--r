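# User-facing fitting front end: mtgrn() returns a classed model object with
# the usual accessor methods.

#' Fit cell type-specific gene regulatory networks on a lineage tree
#'
#' Jointly infers one directed regulator-to-target network per cell type.
#' Each cell type's network is a dependency network: every gene is modeled by
#' a conditional Gaussian given its selected regulators, and regulators are
#' chosen by a greedy score-based search maximising the log posterior
#' (pseudo-likelihood + structure prior). The structure prior combines a
#' logistic edge prior (sparsity `beta0`, motif-prior strength `beta1` acting
#' on per-cell-type prior weights) with a per-edge Markov chain over the
#' lineage tree (`p_root`, `p_gain`, `p_maintain`) that shares edges between
#' related cell types. `mode = "independent"` drops the lineage chain and
#' fits each cell type separately (the single-task ablation).
#'
#' Genes are z-scored within each cell type before fitting (disable with
#' `standardize = FALSE`).
#'
#' @param exprs Named list of genes x cells expression matrices, one per cell
#'   type; all must share the same gene universe.
#' @param tree A [lineage_tree()] whose nodes name the cell types.
#' @param regulators Character vector of candidate regulator genes.
#' @param priors Optional named list (by cell type) of prior-network tables
#'   (regulator, target, weight), e.g. from [prior_from_atac()].
#' @param mode `"multitask"` (default) or `"independent"`.
#' @param beta0,beta1,p_root,p_gain,p_maintain Structure-prior parameters;
#'   see [prior_config()].
#' @param max_regulators,max_rounds,standardize,var_floor See
#'   [inference_config()].
#' @return An object of class `mtgrn` with components `networks` (named list
#'   of edge tables), `models` (fitted conditional Gaussians per cell type),
#'   `tree`, `config`, `trace`, `score_total`, `centers`/`scales` (per cell
#'   type standardization statistics) and `call`.
#' @seealso [grn_stability()] for stability-selection confidence scores.
#' @examples
#' sim <- simulate_lineage_data(simulation_config(
#'   n_regulators = 3, n_genes = 8, n_cells = 60, seed = 1))
#' fit <- mtgrn(sim$expression, sim$tree, sim$regulators, beta0 = -0.5)
#' fit
#' head(coef(fit))
#' @export
mtgrn <- function(exprs, tree, regulators, priors = NULL,
                  mode = c("multitask", "independent"),
                  beta0 = -0.9, beta1 = 0, p_root = 0.2, p_gain = 0.2,
                  p_maintain = 0.8, max_regulators = Inf, max_rounds = 10,
                  standardize = TRUE, var_floor = 1e-6) {
  mode <- match.arg(mode)
  prior <- prior_config(beta0 = beta0, beta1 = beta1, p_root = p_root,
                        p_gain = p_gain, p_maintain = p_maintain,
                        prior_weights = priors)
  cfg <- inference_config(regulators, tree, prior, mode = mode,
                          max_regulators = max_regulators,
                          max_rounds = max_rounds, standardize = standardize,
                          var_floor = var_floor)
  res <- learn_networks(exprs, cfg)

  centers <- lapply(exprs[tree$nodes], rowMeans)
  scales <- lapply(exprs[tree$nodes], function(x) {
    s <- sqrt(rowMeans((x - rowMeans(x))^2))
    s[s < 1e-12] <- 1
    s
  })
  models <- lapply(stats::setNames(tree$nodes, tree$nodes), function(d) {
    x <- exprs[[d]]
    if (standardize) x <- standardize_rows(x)
    net <- res$networks[[d]]
    fits <- lapply(rownames(x), function(g) {
      regs <- net$regulator[net$target == g]
      fit_conditional_gaussian(x, g, regs, var_floor = var_floor)
    })
    stats::setNames(fits, rownames(x))
  })

  structure(
    list(networks = res$networks, models = models, tree = tree, config = cfg,
         trace = res$trace, score_total = res$score_total,
         centers = centers, scales = scales, call = match.call()),
    class = "mtgrn"
  )
}

#' @export
print.mtgrn <- function(x, ...) {
  cat("Multi-task GRN fit (", x$config$mode, " mode)\n", sep = "")
  cat("  cell types:", paste(x$tree$nodes, collapse = ", "),
      "(root:", x$tree$root, ")\n")
  for (d in x$tree$nodes) {
    cat("  ", d, ": ", nrow(x$networks[[d]]), " edges\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mtgrn <- function(object, ...) {
  per_type <- do.call(rbind, lapply(object$tree$nodes, function(d) {
    net <- object$networks[[d]]
    data.frame(
      cell_type = d,
      n_edges = nrow(net),
      n_regulators = length(unique(net$regulator)),
      n_targets = length(unique(net$target)),
      mean_in_degree = if (nrow(net)) mean(table(net$target)) else 0,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(per_type = per_type, mode = object$config$mode,
                 score_total = object$score_total),
            class = "summary.mtgrn")
}

#' @export
print.summary.mtgrn <- function(x, ...) {
  cat("Multi-task GRN fit (", x$mode, " mode), total accepted score ",
      signif(x$score_total, 5), "\n", sep = "")
  print(x$per_type, row.names = FALSE)
  invisible(x)
}

#' Extract edge coefficients from a fitted model
#'
#' @param object An `mtgrn` fit.
#' @param ... Unused.
#' @return A data.frame with one row per inferred edge: cell_type, regulator,
#'   target and the regression coefficient from the target's conditional
#'   Gaussian (on the standardized scale if the fit standardized).
#' @export
coef.mtgrn <- function(object, ...) {
  rows <- lapply(object$tree$nodes, function(d) {
    net <- object$networks[[d]]
    if (!nrow(net)) return(NULL)
    coefs <- mapply(function(u, v) object$models[[d]][[v]]$coefficients[[u]],
                    net$regulator, net$target)
    data.frame(cell_type = d, regulator = net$regulator, target = net$target,
               coefficient = as.numeric(coefs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_type = character(), regulator = character(),
                      target = character(), coefficient = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Predict expression from the fitted conditionals
#'
#' For each gene, the predicted value is the fitted conditional mean given
#' the (standardized) expression of its regulators in `newdata`. Predictions
#' are returned on the original expression scale of the training data.
#'
#' @param object An `mtgrn` fit.
#' @param newdata Genes x cells matrix (defaults to nothing; required).
#' @param cell_type Which cell type's model to use.
#' @param ... Unused.
#' @return A genes x cells matrix of predicted expression.
#' @export
predict.mtgrn <- function(object, newdata, cell_type, ...) {
  if (!cell_type %in% object$tree$nodes) stop("unknown cell type: ", cell_type)
  validate_expression(newdata)
  ctr <- object$centers[[cell_type]]
  scl <- object$scales[[cell_type]]
  genes <- names(object$models[[cell_type]])
  if (!all(genes %in% rownames(newdata))) stop("newdata missing model genes")
  xs <- (newdata[genes, , drop = FALSE] - ctr[genes]) / scl[genes]
  if (!object$config$standardize) xs <- newdata[genes, , drop = FALSE]
  out <- matrix(NA_real_, length(genes), ncol(newdata),
                dimnames = list(genes, colnames(newdata)))
  for (g in genes) {
    fit <- object$models[[cell_type]][[g]]
    mu <- fit$intercept
    if (length(fit$regulators)) {
      mu <- mu + drop(fit$coefficients %*% xs[fit$regulators, , drop = FALSE])
    }
    out[g, ] <- mu
  }
  if (object$config$standardize) out <- out * scl[genes] + ctr[genes]
  out
}

#' @export
residuals.mtgrn <- function(object, exprs, cell_type = NULL, ...) {
  types <- cell_type %||% object$tree$nodes
  res <- lapply(stats::setNames(types, types), function(d) {
    x <- exprs[[d]]
    x[rownames(x), , drop = FALSE] - predict(object, x, d)
  })
  if (length(types) == 1L) res[[1L]] else res
}

#' Plot a fitted network
#'
#' Draws the inferred network of one cell type with igraph when available,
#' otherwise a barplot of regulator out-degrees.
#'
#' @param x An `mtgrn` fit.
#' @param cell_type Cell type to plot (default: the root).
#' @param ... Passed to the underlying plot function.
#' @export
plot.mtgrn <- function(x, cell_type = NULL, ...) {
  d <- cell_type %||% x$tree$root
  net <- x$networks[[d]]
  if (!nrow(net)) {
    graphics::plot.new()
    graphics::title(main = paste0(d, ": empty network"))
    return(invisible(x))
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(net[, c("regulator", "target")])
    plot(g, main = paste0("GRN: ", d), ...)
  } else {
    deg <- sort(table(net$regulator), decreasing = TRUE)
    graphics::barplot(deg, las = 2, main = paste0("Regulator out-degree: ", d), ...)
  }
  invisible(x)
}
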