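# Accessibility/motif-derived prior construction: interval assignment,
# TSS windows, TF-gene scoring and the percentile filter.

test_that("motif-peak assignment uses half-open one-base overlap", {
  motifs <- data.frame(chrom = "chr1", start = 100, end = 110,
                       name = "m1", score = 1)
  # overlapping peak
  hit <- motifs_in_peaks(motifs, data.frame(chrom = "chr1", start = 105, end = 200))
  expect_equal(nrow(hit), 1)
  # half-open boundary: motif [100,110) does not touch peak [110,200)
  miss <- motifs_in_peaks(motifs, data.frame(chrom = "chr1", start = 110, end = 200))
  expect_equal(nrow(miss), 0)
  # different chromosome never overlaps
  expect_equal(nrow(motifs_in_peaks(
    motifs, data.frame(chrom = "chr2", start = 100, end = 110))), 0)
  # malformed interval is rejected with its row
  expect_error(motifs_in_peaks(
    data.frame(chrom = "chr1", start = 10, end = 10, name = "m", score = 1),
    data.frame(chrom = "chr1", start = 0, end = 5)), "row 1")
})

test_that("a motif spanning several peaks is assigned to each (oracle check)", {
  set.seed(77)
  motifs <- data.frame(chrom = "chr1",
                       start = s <- sample(0:500, 40),
                       end = s + sample(5:30, 40, replace = TRUE),
                       name = paste0("m", 1:40), score = runif(40))
  peaks <- data.frame(chrom = "chr1",
                      start = ps <- sample(0:500, 15),
                      end = ps + sample(20:120, 15, replace = TRUE))
  got <- motifs_in_peaks(motifs, peaks)
  # brute-force position-set intersection oracle
  expected <- 0L
  for (i in seq_len(nrow(motifs))) {
    for (j in seq_len(nrow(peaks))) {
      mpos <- seq(motifs$start[i], motifs$end[i] - 1L)
      ppos <- seq(peaks$start[j], peaks$end[j] - 1L)
      if (length(intersect(mpos, ppos))) {
        expected <- expected + 1L
        expect_true(any(got$motif_row == i & got$peak_row == j))
      }
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("peak-to-gene linking honours the +/- window boundary exactly", {
  tss <- data.frame(gene = "g", chrom = "chr1", tss = 10000, strand = "+")
  peak_at <- function(dist) {
    # peak whose nearest covered base is `dist` bp left of the TSS
    data.frame(chrom = "chr1", start = 10000 - dist - 50, end = 10000 - dist + 1)
  }
  expect_equal(peaks_to_genes(peak_at(4999), tss)$gene, "g")
  expect_equal(peaks_to_genes(peak_at(5000), tss)$gene, "g")
  expect_equal(nrow(peaks_to_genes(peak_at(5001), tss)), 0)
  # peak covering the TSS: distance 0
  expect_equal(peaks_to_genes(
    data.frame(chrom = "chr1", start = 9990, end = 10010), tss)$gene, "g")
  # a peak may map to several genes
  tss2 <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                     tss = c(10000, 10400), strand = "+")
  both <- peaks_to_genes(data.frame(chrom = "chr1", start = 10100, end = 10200), tss2)
  expect_setequal(both$gene, c("g1", "g2"))
})

test_that("TF-gene scores take maxima over instances, TSSs and motifs", {
  tss <- data.frame(gene = "g", chrom = "chr1", tss = 1000, strand = "+")
  peaks <- data.frame(chrom = "chr1", start = 900, end = 1100)
  map <- data.frame(motif = c("mA", "mB"), tf = c("TF1", "TF1"))
  # two instances of one motif: max instance score wins
  motifs <- data.frame(chrom = "chr1", start = c(950, 1000), end = c(960, 1010),
                       name = "mA", score = c(2.0, 3.5))
  sc <- score_tf_gene(motifs, motifs_in_peaks(motifs, peaks),
                      peaks_to_genes(peaks, tss), map)
  expect_equal(sc$score, 3.5)
  # two motifs of one TF: max across motifs
  motifs <- data.frame(chrom = "chr1", start = c(950, 1000), end = c(960, 1010),
                       name = c("mA", "mB"), score = c(1.0, 4.0))
  sc <- score_tf_gene(motifs, motifs_in_peaks(motifs, peaks),
                      peaks_to_genes(peaks, tss), map)
  expect_equal(sc$score, 4.0)
  expect_equal(sc$tf, "TF1")
  # instance outside any gene-linked peak: pair absent
  far_peak <- data.frame(chrom = "chr1", start = 50000, end = 50100)
  motifs <- data.frame(chrom = "chr1", start = 50010, end = 50020,
                       name = "mA", score = 9)
  sc <- score_tf_gene(motifs, motifs_in_peaks(motifs, far_peak),
                      peaks_to_genes(far_peak, tss), map)
  expect_equal(nrow(sc), 0)
  # motif without a TF mapping is skipped with a warning
  motifs <- data.frame(chrom = "chr1", start = 950, end = 960,
                       name = "mystery", score = 1)
  expect_warning(score_tf_gene(motifs, motifs_in_peaks(motifs, peaks),
                               peaks_to_genes(peaks, tss), map), "mystery")
})

test_that("percentile filter keeps the top fraction with ties at the cut", {
  sc <- data.frame(tf = "T", gene = paste0("g", 1:10), score = (1:10) / 10)
  out <- percentile_filter(sc, top_frac = 0.2)
  expect_equal(nrow(out), 2)
  expect_setequal(out$target, c("g9", "g10"))
  # weights are percentile ranks in (0,1], monotone with score
  expect_equal(sort(out$weight), c(0.9, 1.0))
  # all-ties degenerate case: everything shares one percentile and is kept
  tied <- data.frame(tf = "T", gene = paste0("g", 1:5), score = 1)
  out <- percentile_filter(tied, top_frac = 0.2)
  expect_equal(nrow(out), 5)
  expect_equal(unique(out$weight), 3 / 5)  # average rank 3 of 5
  # retained scores always dominate dropped ones (sort oracle)
  set.seed(5)
  sc <- data.frame(tf = "T", gene = paste0("g", 1:57), score = rnorm(57))
  out <- percentile_filter(sc, top_frac = 0.2)
  expect_equal(nrow(out), ceiling(0.2 * 57))
  kept <- sc$score[sc$gene %in% out$target]
  expect_gte(min(kept), max(sc$score[!sc$gene %in% out$target]))
  expect_error(percentile_filter(sc[0, ]), "no scored")
})

test_that("per-TF scoping computes the cut within each TF", {
  sc <- data.frame(tf = rep(c("A", "B"), each = 5),
                   gene = paste0("g", 1:10),
                   score = c(1:5, 101:105))
  out <- percentile_filter(sc, top_frac = 0.2, scope = "per_tf")
  # one pair per TF survives despite TF B dominating globally
  expect_setequal(out$regulator, c("A", "B"))
  expect_setequal(out$target, c("g5", "g10"))
})

test_that("planted motifs in a synthetic genome are recovered end to end", {
  # 3 chromosomes, 50 genes; plant one in-window in-peak instance per TF-gene
  # pair for 30 pairs, plus out-of-window decoys that must not appear
  set.seed(99)
  chroms <- paste0("chr", 1:3)
  tss <- data.frame(gene = paste0("g", 1:50),
                    chrom = rep(chroms, length.out = 50),
                    tss = 50000 * (1:50), strand = "+")
  planted <- data.frame(tf = paste0("TF", rep(1:3, 10)),
                        gene = tss$gene[sample(50, 30)])
  planted <- unique(planted)
  map <- data.frame(motif = paste0("mot", 1:3), tf = paste0("TF", 1:3))
  rows_m <- list(); rows_p <- list()
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene[i]
    at <- tss$tss[tss$gene == g] + sample(-4000:4000, 1)
    rows_p[[i]] <- data.frame(chrom = tss$chrom[tss$gene == g],
                              start = at - 100, end = at + 100)
    rows_m[[i]] <- data.frame(chrom = tss$chrom[tss$gene == g],
                              start = at - 5, end = at + 5,
                              name = map$motif[map$tf == planted$tf[i]],
                              score = runif(1, 1, 10))
  }
  # decoys: instances in peaks far beyond the window of any gene
  for (j in 1:5) {
    at <- 50000 * (50 + j) + 25000
    rows_p[[30 + j]] <- data.frame(chrom = "chr1", start = at - 100, end = at + 100)
    rows_m[[30 + j]] <- data.frame(chrom = "chr1", start = at - 5, end = at + 5,
                                   name = "mot1", score = 100)
  }
  motifs <- do.call(rbind, rows_m)
  peaks <- do.call(rbind, rows_p)
  sc <- score_tf_gene(motifs, motifs_in_peaks(motifs, peaks),
                      peaks_to_genes(peaks, tss), map)
  expect_setequal(paste(sc$tf, sc$gene),
                  paste(planted$tf, planted$gene))
  prior <- percentile_filter(sc, top_frac = 1)  # keep all, check weights
  expect_true(all(prior$weight > 0 & prior$weight <= 1))
})
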