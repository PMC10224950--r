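# Construction of accessibility/motif-derived prior networks: map motif
# instances into accessible peaks, peaks to genes near a TSS, score TF-gene
# pairs by maximum motif score, and keep the top fraction by percentile.
#
# All genomic coordinates follow the BED convention: 0-based, half-open
# [start, end). Interval arithmetic is done directly on integers so the
# +/- window boundary semantics are exact.

check_intervals <- function(x, need_score = FALSE, what = "interval") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) stop(what, " table needs chrom, start, end columns")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop("malformed ", what, " at row ", bad[1L], ": need 0 <= start < end")
  }
  if (need_score) {
    if (!"score" %in% names(x)) stop(what, " table needs a score column")
    if (any(!is.finite(x$score))) stop("non-finite score in ", what, " table")
  }
  invisible(x)
}

#' Assign motif instances to accessibility peaks
#'
#' A motif instance is assigned to every peak it overlaps by at least one
#' base (half-open interval arithmetic).
#'
#' @param motifs data.frame of motif instances: chrom, start, end, name
#'   (motif identifier), score.
#' @param peaks data.frame of peaks: chrom, start, end (optionally name).
#' @return data.frame with columns motif_row, peak_row (row indices into the
#'   inputs).
#' @export
motifs_in_peaks <- function(motifs, peaks) {
  check_intervals(motifs, need_score = TRUE, what = "motif")
  check_intervals(peaks, what = "peak")
  out <- list()
  for (ch in intersect(unique(motifs$chrom), unique(peaks$chrom))) {
    mi <- which(motifs$chrom == ch)
    pi <- which(peaks$chrom == ch)
    # all pairs on this chromosome; overlap iff start1 < end2 and start2 < end1
    grid <- expand.grid(m = mi, p = pi, KEEP.OUT.ATTRS = FALSE)
    hit <- motifs$start[grid$m] < peaks$end[grid$p] &
      peaks$start[grid$p] < motifs$end[grid$m]
    out[[ch]] <- grid[hit, , drop = FALSE]
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(m = integer(), p = integer())
  data.frame(motif_row = res$m, peak_row = res$p, row.names = NULL)
}

#' Assign peaks to genes near a transcription start site
#'
#' A peak is assigned to a gene when the minimum distance between any
#' position covered by the peak and any TSS of the gene is at most `window`
#' base pairs (strand-ignored; a peak may map to several genes).
#'
#' @param peaks data.frame: chrom, start, end (0-based half-open).
#' @param tss data.frame: gene, chrom, tss (0-based position); a gene may
#'   have several rows.
#' @param window Distance cutoff in bp (default 5000).
#' @return data.frame with columns peak_row, gene.
#' @export
peaks_to_genes <- function(peaks, tss, window = 5000) {
  check_intervals(peaks, what = "peak")
  if (!all(c("gene", "chrom", "tss") %in% names(tss))) {
    stop("tss table needs gene, chrom, tss columns")
  }
  if (window <= 0) stop("window must be positive")
  out <- list()
  for (ch in intersect(unique(peaks$chrom), unique(tss$chrom))) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    grid <- expand.grid(p = pi, t = ti, KEEP.OUT.ATTRS = FALSE)
    # distance from TSS point to interval [start, end): 0 inside, else gap to
    # the nearest covered position (end - 1 is the last covered base)
    d <- pmax(0, peaks$start[grid$p] - tss$tss[grid$t],
              tss$tss[grid$t] - (peaks$end[grid$p] - 1L))
    hit <- d <= window
    out[[ch]] <- data.frame(peak_row = grid$p[hit], gene = tss$gene[grid$t[hit]])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(peak_row = integer(), gene = character())
  unique(res[order(res$peak_row, res$gene), , drop = FALSE])
}

#' Score TF-gene pairs from motif instances in gene-linked peaks
#'
#' For each (TF, gene) pair the raw score is the maximum motif-instance score
#' over all instances of any of the TF's motifs that fall inside a peak
#' assigned to the gene.
#'
#' @param motifs Motif-instance table (chrom, start, end, name, score).
#' @param motif_assign Output of [motifs_in_peaks()].
#' @param gene_assign Output of [peaks_to_genes()].
#' @param motif_tf data.frame mapping motif name to TF: columns motif, tf.
#' @return data.frame with columns tf, gene, score. Motifs without a TF
#'   mapping are skipped with a warning.
#' @export
score_tf_gene <- function(motifs, motif_assign, gene_assign, motif_tf) {
  if (!all(c("motif", "tf") %in% names(motif_tf))) {
    stop("motif_tf needs motif and tf columns")
  }
  if (!nrow(motif_assign) || !nrow(gene_assign)) {
    return(data.frame(tf = character(), gene = character(), score = numeric()))
  }
  joined <- merge(motif_assign, gene_assign, by = "peak_row")
  joined$motif <- motifs$name[joined$motif_row]
  joined$score <- motifs$score[joined$motif_row]
  unmapped <- setdiff(unique(joined$motif), motif_tf$motif)
  if (length(unmapped)) {
    warning("skipping motifs without a TF mapping: ",
            paste(unmapped, collapse = ", "))
  }
  joined$tf <- motif_tf$tf[match(joined$motif, motif_tf$motif)]
  joined <- joined[!is.na(joined$tf), , drop = FALSE]
  if (!nrow(joined)) {
    return(data.frame(tf = character(), gene = character(), score = numeric()))
  }
  agg <- stats::aggregate(score ~ tf + gene, data = joined, FUN = max)
  agg <- agg[order(agg$tf, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("tf", "gene", "score")]
}

#' Percentile-filter raw TF-gene scores into prior edge weights
#'
#' Converts raw scores to empirical percentile ranks (rank / n, average rank
#' for ties) and retains the top `top_frac` of pairs: the threshold is the
#' `ceil(top_frac * n)`-th largest score and all pairs scoring at least the
#' threshold are kept, so ties at the cut are all retained. Retained weights
#' lie in (0, 1\] and are monotone in the raw score.
#'
#' @param scores data.frame with columns tf, gene, score (at least one row).
#' @param top_frac Fraction of pairs to retain (default 0.2).
#' @param scope `"global"`: percentiles over all pairs together (default);
#'   `"per_tf"`: percentiles and the cut computed within each TF's pairs.
#' @return data.frame with columns regulator, target, weight (the percentile
#'   rank), suitable as a `prior_weights` entry for [prior_config()].
#' @export
percentile_filter <- function(scores, top_frac = 0.2,
                              scope = c("global", "per_tf")) {
  scope <- match.arg(scope)
  if (!nrow(scores)) stop("no scored TF-gene pairs to filter")
  filt <- function(df) {
    n <- nrow(df)
    pct <- rank(df$score, ties.method = "average") / n
    k <- ceiling(top_frac * n)
    thr <- sort(df$score, decreasing = TRUE)[k]
    keep <- df$score >= thr
    data.frame(regulator = df$tf[keep], target = df$gene[keep],
               weight = pct[keep], stringsAsFactors = FALSE)
  }
  out <- if (scope == "global") {
    filt(scores)
  } else {
    do.call(rbind, lapply(split(scores, scores$tf), filt))
  }
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a prior network from motifs, peaks and TSS annotations
#'
#' End-to-end wrapper for one cell type: motif instances are intersected with
#' the cell type's accessibility peaks, peaks are linked to genes within
#' `window` bp of a TSS, TF-gene pairs are scored by maximum motif score and
#' percentile-filtered to the top fraction.
#'
#' @inheritParams score_tf_gene
#' @inheritParams peaks_to_genes
#' @inheritParams percentile_filter
#' @param peaks Peak table for the cell type.
#' @return Prior-network data.frame (regulator, target, weight).
#' @export
prior_from_atac <- function(motifs, peaks, tss, motif_tf, window = 5000,
                            top_frac = 0.2, scope = c("global", "per_tf")) {
  ma <- motifs_in_peaks(motifs, peaks)
  ga <- peaks_to_genes(peaks, tss, window = window)
  sc <- score_tf_gene(motifs, ma, ga, motif_tf)
  if (!nrow(sc)) {
    return(data.frame(regulator = character(), target = character(),
                      weight = numeric()))
  }
  percentile_filter(sc, top_frac = top_frac, scope = match.arg(scope))
}
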