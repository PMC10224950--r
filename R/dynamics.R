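# Network rewiring analyses on stability-selected networks: k-means edge
# clustering with silhouette-based model selection, and LDA topic networks
# over TF-per-cell-type documents.

#' Restrict a confidence matrix to the union of top-k edges
#'
#' Rows are the union over cell types of each cell type's top-k edges by
#' confidence; entries are the original confidences (0 where an edge was
#' never inferred in a cell type).
#'
#' @param conf An `edge_confidence` object.
#' @param k_per_type Number of top edges per cell type.
#' @return An `edge_confidence` object with the restricted row set.
#' @export
build_edge_matrix <- function(conf, k_per_type) {
  if (k_per_type < 1) stop("k_per_type must be >= 1")
  edges <- attr(conf, "edges")
  keys <- character()
  for (d in colnames(conf)) {
    top <- suppressWarnings(top_k_edges(conf, d, k_per_type))
    keys <- union(keys, edge_key(top$regulator, top$target))
  }
  keep <- rownames(conf) %in% keys
  edge_confidence(unclass(conf)[keep, , drop = FALSE],
                  edges[keep, , drop = FALSE])
}

# mean silhouette width of a clustering (requires >= 2 clusters)
mean_silhouette <- function(assign, dmat) {
  sil <- cluster::silhouette(assign, dmat)
  mean(sil[, "sil_width"])
}

#' Cluster edges by their confidence profiles
#'
#' Runs k-means (10 restarts, fixed seed) on the edge x cell-type confidence
#' matrix for each k in `k_range`, computes the mean silhouette width, and
#' keeps the smallest k whose silhouette is within 1% of the maximum over
#' the range. If all rows are identical the clustering is degenerate and a
#' single cluster is returned with a warning.
#'
#' @param mat An `edge_confidence` object (typically from
#'   [build_edge_matrix()]) or plain numeric matrix with edge-key rownames.
#' @param k_range Candidate cluster counts (default 5:30).
#' @param seed Integer seed.
#' @return List of class `edge_clustering`: `k` (chosen), `assignment`
#'   (named integer vector), `clusters` (list with member edges, mean
#'   confidence profile and size per cluster) and `silhouettes` (named by k).
#' @export
kmeans_edge_clusters <- function(mat, k_range = 5:30, seed = 1) {
  x <- unclass(mat)
  edges <- attr(mat, "edges")
  if (is.null(edges)) {
    parts <- strsplit(rownames(x), "\r", fixed = TRUE)
    edges <- data.frame(regulator = vapply(parts, `[`, character(1), 1),
                        target = vapply(parts, `[`, character(1), 2))
  }
  n <- nrow(x)
  if (n < 2 || all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    warning("degenerate confidence matrix; returning a single cluster")
    return(make_edge_clustering(rep(1L, n), x, edges, k = 1L,
                                sil = stats::setNames(numeric(), character())))
  }
  dmat <- stats::dist(x)
  sils <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  assigns <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k >= n || k < 2) next  # not enough rows for this k
    km <- with_seed(derive_seed(seed, i),
                    stats::kmeans(x, centers = k, nstart = 10, iter.max = 50))
    sils[i] <- mean_silhouette(km$cluster, dmat)
    assigns[[i]] <- km$cluster
  }
  if (all(is.na(sils))) stop("no feasible k in k_range for ", n, " edges")
  best <- max(sils, na.rm = TRUE)
  chosen <- which(!is.na(sils) & sils >= 0.99 * best)[1L]
  make_edge_clustering(assigns[[chosen]], x, edges, k = k_range[chosen],
                       sil = sils[!is.na(sils)])
}

make_edge_clustering <- function(assign, x, edges, k, sil) {
  names(assign) <- rownames(x)
  clusters <- lapply(sort(unique(assign)), function(cl) {
    idx <- which(assign == cl)
    list(cluster_id = cl,
         edges = edges[idx, , drop = FALSE],
         profile = if (length(idx)) colMeans(x[idx, , drop = FALSE]) else
           stats::setNames(numeric(ncol(x)), colnames(x)),
         size = length(idx))
  })
  structure(list(k = k, assignment = assign, clusters = clusters,
                 silhouettes = sil),
            class = "edge_clustering")
}

#' @export
print.edge_clustering <- function(x, ...) {
  cat("Edge clustering: k =", x$k, "over", length(x$assignment), "edges\n")
  sizes <- vapply(x$clusters, `[[`, numeric(1), "size")
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Top regulators per edge cluster
#'
#' For each cluster, counts each regulator's member edges (targets), keeps
#' regulators with at least `min_targets` and reports the `top_n` by target
#' count (ties broken alphabetically).
#'
#' @param clustering An `edge_clustering` object (or list of edge tables).
#' @param min_targets Minimum member-edge count (default 10).
#' @param top_n Regulators reported per cluster (default 5).
#' @return data.frame: cluster_id, regulator, n_targets, rank.
#' @export
top_regulators <- function(clustering, min_targets = 10, top_n = 5) {
  groups <- if (inherits(clustering, "edge_clustering")) {
    stats::setNames(lapply(clustering$clusters, `[[`, "edges"),
                    vapply(clustering$clusters, `[[`, numeric(1), "cluster_id"))
  } else {
    clustering
  }
  rows <- lapply(names(groups), function(cl) {
    cnt <- table(groups[[cl]]$regulator)
    cnt <- cnt[cnt >= min_targets]
    if (!length(cnt)) return(NULL)
    ord <- order(-cnt, names(cnt))
    sel <- ord[seq_len(min(top_n, length(cnt)))]
    data.frame(cluster_id = cl, regulator = names(cnt)[sel],
               n_targets = as.integer(cnt[sel]),
               rank = seq_along(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster_id = character(), regulator = character(),
                      n_targets = integer(), rank = integer())
  }
  rownames(out) <- NULL
  out
}

#' Fit an LDA topic model over TF-per-cell-type documents
#'
#' Each (TF, cell type) pair with at least one target in that cell type's
#' network is a document; its words are the TF's targets (binary occurrence).
#' Fitting is by collapsed Gibbs sampling with symmetric Dirichlet priors
#' (document-topic `alpha = 1/K`, topic-word `eta = 0.01`) for a fixed
#' number of iterations, so results are reproducible for a given seed.
#'
#' @param networks Named list of edge tables (e.g. the 80% confidence
#'   networks from [consensus_networks()]).
#' @param n_topics Number of topics K (default 10).
#' @param seed Integer seed.
#' @param alpha,eta Dirichlet hyperparameters (defaults 1/K and 0.01).
#' @param iterations Gibbs iterations (default 1000).
#' @return Object of class `topic_model`: `theta` (documents x K, rows sum
#'   to 1), `phi` (K x vocabulary, rows sum to 1), `docs` (data.frame tf,
#'   cell_type) and `vocab`.
#' @export
fit_lda <- function(networks, n_topics = 10, seed = 1, alpha = 1 / n_topics,
                    eta = 0.01, iterations = 1000) {
  if (n_topics < 1) stop("n_topics must be >= 1")
  docs <- list()
  meta <- list()
  for (d in names(networks)) {
    net <- networks[[d]]
    if (is.null(net) || !nrow(net)) next
    for (tf in sort(unique(net$regulator))) {
      words <- sort(unique(net$target[net$regulator == tf]))
      docs[[length(docs) + 1L]] <- words
      meta[[length(meta) + 1L]] <- data.frame(tf = tf, cell_type = d,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(docs)) stop("empty corpus: no documents with at least one target")
  vocab <- sort(unique(unlist(docs)))
  V <- length(vocab)
  M <- length(docs)
  K <- n_topics
  wid <- lapply(docs, match, vocab)

  with_seed(seed, {
    z <- lapply(wid, function(w) sample.int(K, length(w), replace = TRUE))
    ndk <- matrix(0L, M, K)
    nkv <- matrix(0L, K, V)
    nk <- integer(K)
    for (m in seq_len(M)) {
      for (j in seq_along(wid[[m]])) {
        t <- z[[m]][j]
        ndk[m, t] <- ndk[m, t] + 1L
        nkv[t, wid[[m]][j]] <- nkv[t, wid[[m]][j]] + 1L
        nk[t] <- nk[t] + 1L
      }
    }
    if (K > 1L) {
      for (it in seq_len(iterations)) {
        for (m in seq_len(M)) {
          wm <- wid[[m]]
          for (j in seq_along(wm)) {
            t <- z[[m]][j]
            v <- wm[j]
            ndk[m, t] <- ndk[m, t] - 1L
            nkv[t, v] <- nkv[t, v] - 1L
            nk[t] <- nk[t] - 1L
            p <- (ndk[m, ] + alpha) * (nkv[, v] + eta) / (nk + V * eta)
            t <- sample.int(K, 1L, prob = p)
            z[[m]][j] <- t
            ndk[m, t] <- ndk[m, t] + 1L
            nkv[t, v] <- nkv[t, v] + 1L
            nk[t] <- nk[t] + 1L
          }
        }
      }
    }
    theta <- (ndk + alpha) / (rowSums(ndk) + K * alpha)
    phi <- (nkv + eta) / (nk + V * eta)
    meta <- do.call(rbind, meta)
    rownames(theta) <- paste(meta$tf, meta$cell_type, sep = "@")
    colnames(phi) <- vocab
    structure(list(theta = theta, phi = phi, docs = meta, vocab = vocab,
                   n_topics = K, alpha = alpha, eta = eta,
                   iterations = iterations, seed = seed),
              class = "topic_model")
  })
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model:", x$n_topics, "topics,", nrow(x$docs),
      "documents,", length(x$vocab), "words\n")
  invisible(x)
}

#' Per-topic induced subnetworks
#'
#' Assigns each target gene to its maximum-probability topic (argmax over
#' `phi` columns, ties to the lower topic index) and each regulator, per
#' cell type, to its document's maximum-probability topic (argmax of
#' `theta`). The topic-t subnetwork of cell type d contains the edges of d's
#' network whose regulator document and target are both assigned to topic t.
#'
#' @param model A fitted `topic_model`.
#' @param networks The same named list of edge tables used for the fit.
#' @return List with `gene_topic` (named integer vector), `doc_topic`
#'   (named by tf\@cell_type), `subnetworks` (nested list
#'   `[[topic]][[cell_type]]` of edge tables) and `regulator_degrees`
#'   (data.frame topic, cell_type, regulator, degree).
#' @export
topic_subnetworks <- function(model, networks) {
  gene_topic <- apply(model$phi, 2, which.max)  # ties -> lower index
  doc_topic <- apply(model$theta, 1, which.max)
  subs <- vector("list", model$n_topics)
  degs <- list()
  for (t in seq_len(model$n_topics)) {
    subs[[t]] <- lapply(stats::setNames(names(networks), names(networks)),
                        function(d) {
      net <- networks[[d]]
      if (is.null(net) || !nrow(net)) return(grn_edges())
      dkey <- paste(net$regulator, d, sep = "@")
      keep <- !is.na(doc_topic[dkey]) & doc_topic[dkey] == t &
        gene_topic[net$target] == t
      keep[is.na(keep)] <- FALSE
      net[keep, , drop = FALSE]
    })
    for (d in names(networks)) {
      sub <- subs[[t]][[d]]
      if (nrow(sub)) {
        cnt <- table(sub$regulator)
        degs[[length(degs) + 1L]] <- data.frame(
          topic = t, cell_type = d, regulator = names(cnt),
          degree = as.integer(cnt), stringsAsFactors = FALSE)
      }
    }
  }
  list(gene_topic = gene_topic, doc_topic = doc_topic, subnetworks = subs,
       regulator_degrees = if (length(degs)) do.call(rbind, degs) else
         data.frame(topic = integer(), cell_type = character(),
                    regulator = character(), degree = integer()))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Tests every (query set, annotation set) pair for overlap enrichment with
#' an upper-tail hypergeometric test on the given universe, and corrects all
#' p-values jointly by Benjamini-Hochberg. Significance is called at
#' FDR < `fdr`.
#'
#' @param query_sets Named list of gene vectors (e.g. per-topic gene sets).
#' @param annotation_sets Named list of gene vectors (user-supplied, e.g. GO
#'   process members).
#' @param universe Character vector containing every tested gene.
#' @param fdr FDR threshold (default 0.01).
#' @return data.frame: query, annotation, overlap, query_size,
#'   annotation_size, p_value, fdr, significant.
#' @export
geneset_enrichment <- function(query_sets, annotation_sets, universe,
                               fdr = 0.01) {
  if (!length(universe)) stop("universe is empty")
  universe <- unique(universe)
  allg <- unique(c(unlist(query_sets), unlist(annotation_sets)))
  if (!all(allg %in% universe)) stop("universe must contain all tested genes")
  N <- length(universe)
  rows <- list()
  for (q in names(query_sets)) {
    qs <- unique(query_sets[[q]])
    for (a in names(annotation_sets)) {
      as_ <- unique(annotation_sets[[a]])
      ov <- length(intersect(qs, as_))
      p <- stats::phyper(ov - 1, length(as_), N - length(as_), length(qs),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, annotation = a, overlap = ov, query_size = length(qs),
        annotation_size = length(as_), p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr
  rownames(out) <- NULL
  out
}
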