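# Rewiring analyses: edge clustering, topic models, enrichment.

mk_conf <- function(mat, regs, tgts) {
  edge_confidence(mat, data.frame(regulator = regs, target = tgts))
}

test_that("edge matrix restriction takes the union of per-type top-k rows", {
  m <- cbind(A = c(0.9, 0.8, 0.1, 0.0), B = c(0.9, 0.0, 0.0, 0.7))
  conf <- mk_conf(m, paste0("r", 1:4), paste0("t", 1:4))
  # identical top sets collapse to k rows; here A and B share r1->t1
  r2 <- build_edge_matrix(conf, 2)
  expect_setequal(edge_keys(attr(r2, "edges")),
                  c("r1->t1", "r2->t2", "r4->t4"))
  # values are looked up from the source matrix (zeros preserved)
  expect_equal(unname(r2[mtgrn:::edge_key("r4", "t4"), ]), c(0, 0.7))
  # fully disjoint top-k sets across M types give M*k rows
  m2 <- cbind(A = c(0.9, 0.8, 0, 0), B = c(0, 0, 0.9, 0.8))
  conf2 <- mk_conf(m2, paste0("r", 1:4), paste0("t", 1:4))
  expect_equal(nrow(build_edge_matrix(conf2, 2)), 4)
})

test_that("k-means edge clustering finds separated blocks and partitions rows", {
  # two well-separated blobs in confidence space
  set.seed(44)
  blob <- function(center, n) {
    t(replicate(n, pmin(1, pmax(0, center + runif(3, -0.03, 0.03)))))
  }
  m <- rbind(blob(c(0.9, 0.9, 0.05), 20), blob(c(0.05, 0.05, 0.9), 20))
  colnames(m) <- c("A", "B", "C")
  conf <- mk_conf(m, paste0("r", 1:40), paste0("t", 1:40))
  cl <- kmeans_edge_clusters(conf, k_range = 2:6, seed = 5)
  expect_equal(cl$k, 2)
  expect_equal(sort(vapply(cl$clusters, `[[`, numeric(1), "size")), c(20, 20))
  # perfect assignment: each blob is one cluster
  expect_equal(length(unique(cl$assignment[1:20])), 1L)
  expect_equal(length(unique(cl$assignment[21:40])), 1L)
  # clusters partition the rows exactly
  expect_equal(sum(vapply(cl$clusters, `[[`, numeric(1), "size")), 40)
  expect_setequal(names(cl$assignment), rownames(m <- unclass(conf)))
  # mean profiles equal the arithmetic mean of member rows
  for (c2 in cl$clusters) {
    idx <- mtgrn:::edge_key(c2$edges$regulator, c2$edges$target)
    expect_equal(c2$profile, colMeans(unclass(conf)[idx, , drop = FALSE]))
  }
  # degenerate identical rows: single cluster with a warning
  same <- mk_conf(matrix(0.5, 5, 2, dimnames = list(NULL, c("A", "B"))),
                  paste0("r", 1:5), paste0("t", 1:5))
  expect_warning(cl0 <- kmeans_edge_clusters(same, k_range = 2:4), "degenerate")
  expect_equal(cl0$k, 1L)
})

test_that("planted cell-type-specific edge blocks are recovered across seeds", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    blocks <- lapply(1:3, function(b) {
      center <- c(0.1, 0.1, 0.1)
      center[b] <- 0.9
      t(replicate(15, pmin(1, pmax(0, center + rnorm(3, 0, 0.05)))))
    })
    m <- do.call(rbind, blocks)
    colnames(m) <- c("A", "B", "C")
    conf <- mk_conf(m, paste0("r", 1:45), paste0("t", 1:45))
    cl <- kmeans_edge_clusters(conf, k_range = 2:6, seed = s)
    mclust::adjustedRandIndex(cl$assignment, rep(1:3, each = 15))
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.9)
})

test_that("top regulators honour the minimum-target and tie-break rules", {
  edges <- data.frame(
    regulator = c(rep("A", 30), rep("B", 12), rep("C", 11), rep("D", 9),
                  rep("E", 12)),
    target = paste0("t", 1:74))
  tab <- top_regulators(list(cl1 = edges), min_targets = 10, top_n = 5)
  expect_false("D" %in% tab$regulator)  # 9 targets < 10
  expect_equal(tab$regulator, c("A", "B", "E", "C"))  # tie 12/12: B before E
  expect_equal(tab$n_targets, c(30, 12, 12, 11))
  top2 <- top_regulators(list(cl1 = edges), min_targets = 10, top_n = 2)
  expect_equal(top2$regulator, c("A", "B"))
})

test_that("single-topic LDA reduces to global word frequencies", {
  nets <- list(A = grn_edges(c("tf1", "tf1", "tf2"), c("g1", "g2", "g1")))
  model <- fit_lda(nets, n_topics = 1, seed = 1, eta = 1e-9, iterations = 10)
  expect_equal(unname(model$theta[, 1]), c(1, 1))
  freq <- c(g1 = 2, g2 = 1) / 3
  expect_equal(model$phi[1, ], freq, tolerance = 1e-6)
})

test_that("LDA rows normalize and runs are reproducible at a fixed seed", {
  set.seed(55)
  nets <- list(
    A = grn_edges(rep(paste0("tf", 1:4), each = 4),
                  paste0("g", sample(12, 16, replace = TRUE) )[1:16]),
    B = grn_edges(rep(paste0("tf", 1:3), each = 3),
                  paste0("g", sample(12, 9, replace = TRUE))[1:9]))
  nets <- lapply(nets, function(n) n[n$regulator != n$target, ])
  model <- fit_lda(nets, n_topics = 3, seed = 9, iterations = 50)
  expect_equal(unname(rowSums(model$theta)), rep(1, nrow(model$theta)),
               tolerance = 1e-8)
  expect_equal(unname(rowSums(model$phi)), rep(1, 3), tolerance = 1e-8)
  model2 <- fit_lda(nets, n_topics = 3, seed = 9, iterations = 50)
  expect_identical(model$theta, model2$theta)
  expect_identical(model$phi, model2$phi)
  expect_error(fit_lda(list(A = grn_edges()), n_topics = 2), "empty corpus")
})

test_that("disjoint vocabularies separate into their own topics", {
  # documents over two non-overlapping word sets; the dominant topic of each
  # document should align with its vocabulary in nearly all seeded runs
  nets <- list(
    A = grn_edges(rep(paste0("ftf", 1:4), each = 5), rep(paste0("fg", 1:5), 4)),
    B = grn_edges(rep(paste0("stf", 1:4), each = 5), rep(paste0("sg", 1:5), 4)))
  ok <- 0
  for (s in 1:20) {
    model <- fit_lda(nets, n_topics = 2, seed = s, iterations = 200)
    dom <- apply(model$theta, 1, which.max)
    groups <- split(dom, model$docs$cell_type)
    aligned <- length(unique(groups$A)) == 1 && length(unique(groups$B)) == 1 &&
      groups$A[1] != groups$B[1]
    ok <- ok + aligned
  }
  expect_gte(ok / 20, 0.95)
})

test_that("topic subnetworks induce, partition and reduce correctly", {
  nets <- list(A = grn_edges(c("tf1", "tf1", "tf2"), c("g1", "g2", "g3")))
  # single topic: the subnetwork is the full network
  m1 <- fit_lda(nets, n_topics = 1, seed = 1, iterations = 10)
  sub1 <- topic_subnetworks(m1, nets)
  expect_setequal(edge_keys(sub1$subnetworks[[1]]$A), edge_keys(nets$A))
  # gene assignment is exclusive: a gene appears in exactly one topic
  nets2 <- list(
    A = grn_edges(rep("ftf", 4), paste0("fg", 1:4)),
    B = grn_edges(rep("stf", 4), paste0("sg", 1:4)))
  m2 <- fit_lda(nets2, n_topics = 2, seed = 3, iterations = 200)
  sub2 <- topic_subnetworks(m2, nets2)
  per_topic_genes <- lapply(1:2, function(t) {
    names(sub2$gene_topic)[sub2$gene_topic == t]
  })
  expect_equal(length(intersect(per_topic_genes[[1]], per_topic_genes[[2]])), 0L)
  expect_setequal(unlist(per_topic_genes), m2$vocab)
  # an edge whose target sits in another topic is excluded
  for (t in 1:2) {
    for (d in names(nets2)) {
      sub <- sub2$subnetworks[[t]][[d]]
      if (nrow(sub)) {
        expect_true(all(sub2$gene_topic[sub$target] == t))
      }
    }
  }
})

test_that("gene-set enrichment matches exact hypergeometric and BH step-up", {
  universe <- paste0("g", 1:50)
  qs <- list(topic1 = paste0("g", 1:5))
  as_ <- list(set1 = paste0("g", 1:5), set2 = paste0("g", 40:44))
  tab <- geneset_enrichment(qs, as_, universe, fdr = 0.01)
  exact <- 1 / choose(50, 5)
  expect_equal(tab$p_value[tab$annotation == "set1"], exact, tolerance = 1e-12)
  expect_true(tab$significant[tab$annotation == "set1"])
  expect_gt(tab$p_value[tab$annotation == "set2"], 0.4)
  expect_false(tab$significant[tab$annotation == "set2"])
  expect_error(geneset_enrichment(qs, as_, character()), "empty")
  expect_error(geneset_enrichment(qs, as_, paste0("g", 1:10)), "must contain")

  # BH correction agrees with a hand-rolled step-up rule on random p-vectors
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(66)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})
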