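# Readers/writers for the package's TSV formats and the small end-to-end
# fixture generator used by the test suite.
#
# Formats (all tab-separated, names case-sensitive):
#   expression: first column gene name, header row of cell ids, numeric body
#   network:    columns regulator, target, weight
#   lineage:    columns child, parent; the root row has parent "-"
#   intervals:  BED-like, columns chrom, start, end [, name, score, strand]
#   tss:        columns gene, chrom, tss, strand

#' Read an expression matrix TSV
#'
#' @param path File path.
#' @return Numeric genes x cells matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column and >=1 cell: ", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene name in ", path, ": ", genes[duplicated(genes)][1L])
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      stop("non-numeric expression values in ", path, ", column ", names(body)[j])
    }
  }
  x <- as.matrix(body)
  rownames(x) <- genes
  validate_expression(x)
  x
}

#' Write an expression matrix TSV
#' @param expr Genes x cells matrix.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network TSV (regulator, target, weight)
#' @param path File path.
#' @return Edge table data.frame.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(df))) {
    stop("network file needs regulator and target columns: ", path)
  }
  grn_edges(df$regulator, df$target, df$weight %||% 1)
}

#' Write a network TSV
#' @param net Edge table.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lineage tree TSV (child, parent; root parent "-")
#' @param path File path.
#' @return A [lineage_tree()].
#' @export
read_lineage_tree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(df))) {
    stop("lineage file needs child and parent columns: ", path)
  }
  parent <- stats::setNames(ifelse(df$parent == "-", NA_character_,
                                   as.character(df$parent)),
                            as.character(df$child))
  lineage_tree(df$child, parent)
}

#' Write a lineage tree TSV
#' @param tree A [lineage_tree()].
#' @param path File path.
#' @export
write_lineage_tree <- function(tree, path) {
  df <- data.frame(child = tree$nodes,
                   parent = ifelse(is.na(tree$parent), "-", tree$parent))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval TSV
#' @param path File path.
#' @param need_score Require a score column (motif instances).
#' @return data.frame with chrom, start, end and any extra columns.
#' @export
read_intervals <- function(path, need_score = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_intervals(df, need_score = need_score, what = basename(path))
  df
}

#' Export a lineage tree in Newick format
#' @param tree A [lineage_tree()].
#' @return A Newick string (rooted, no branch lengths).
#' @export
tree_to_newick <- function(tree) {
  rec <- function(nd) {
    kids <- tree_children(tree, nd)
    if (!length(kids)) return(nd)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", nd)
  }
  paste0(rec(tree$root), ";")
}

#' Generate a small, fully deterministic fixture directory
#'
#' Writes a reduced-scale dataset exercising the whole pipeline: 5
#' regulators among 20 genes on a linear 3-node lineage, 100 cells per cell
#' type (default 50% dropout), plus prior networks for two of the three cell
#' types and the regulator list. Byte-identical across runs for a given
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @return Invisibly, the list of written file paths.
#' @export
make_fixture <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulation_config(n_regulators = 5, n_genes = 20, n_cells = 100,
                           sparsity = 0.5, max_in_degree = 2,
                           mean_shift = 0.5, seed = seed)
  sim <- simulate_lineage_data(cfg)
  paths <- character()
  for (d in sim$tree$nodes) {
    p <- file.path(dir, paste0("expr_", d, ".tsv"))
    write_expression(round(sim$expression[[d]], 6), p)
    paths <- c(paths, p)
    p <- file.path(dir, paste0("truenet_", d, ".tsv"))
    write_network(sim$networks[[d]], p)
    paths <- c(paths, p)
  }
  # priors for two of the three cell types: true edges with high weights plus
  # a few decoys, mimicking an accessibility-derived prior
  for (d in sim$tree$nodes[1:2]) {
    net <- sim$networks[[d]]
    nkeep <- max(1L, floor(nrow(net) / 2))
    pw <- with_seed(derive_seed(seed, 50 + match(d, sim$tree$nodes)), {
      keep <- sort(sample.int(nrow(net), nkeep))
      decoy_r <- sample(sim$regulators, 3, replace = TRUE)
      decoy_t <- sample(sim$genes, 3, replace = TRUE)
      ok <- decoy_r != decoy_t
      data.frame(
        regulator = c(net$regulator[keep], decoy_r[ok]),
        target = c(net$target[keep], decoy_t[ok]),
        weight = round(c(stats::runif(nkeep, 0.8, 1), stats::runif(sum(ok), 0.2, 0.5)), 4),
        stringsAsFactors = FALSE)
    })
    pw <- unique(pw[order(pw$regulator, pw$target), ])
    p <- file.path(dir, paste0("prior_", d, ".tsv"))
    write_network(grn_edges(pw$regulator, pw$target, pw$weight), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "lineage.tsv")
  write_lineage_tree(sim$tree, p)
  paths <- c(paths, p)
  p <- file.path(dir, "regulators.txt")
  writeLines(sim$regulators, p)
  paths <- c(paths, p)
  invisible(paths)
}
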