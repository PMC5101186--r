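# convert a 0-based half-open peak_set to a 1-based closed GRanges;
# seqlevels can be supplied so two sets share a common level universe
peaks_to_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(factor(peaks$chrom, levels = seqlevels),
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Overlap summary between two peak sets
#'
#' An interval of A counts as overlapping when it shares at least `min_bp`
#' bases with any interval of B, under half-open coordinate arithmetic
#' (touching intervals share 0 bases). Also reports a base-pair Jaccard
#' index over the merged footprints of the two sets, since a peak-count
#' overlap and a base-pair overlap can tell different stories.
#' Chromosomes present in only one set are treated as non-overlapping with
#' a warning.
#'
#' @param peaks_a,peaks_b [peak_set()] objects on the same genome.
#' @param min_bp Minimum shared bases (default 1).
#' @return List of class `overlap_summary`: `n_A`, `n_B`,
#'   `n_A_overlapping_B`, `fraction_A_overlapping`,
#'   `percent_A_overlapping`, `jaccard_bp`.
#' @export
overlap_peaks <- function(peaks_a, peaks_b, min_bp = 1) {
  stopifnot(inherits(peaks_a, "peak_set"), inherits(peaks_b, "peak_set"))
  only <- c(setdiff(unique(peaks_a$chrom), unique(peaks_b$chrom)),
            setdiff(unique(peaks_b$chrom), unique(peaks_a$chrom)))
  if (length(only))
    warning("chromosome(s) present in only one set: ",
            paste(only, collapse = ", "))
  lv <- union(unique(peaks_a$chrom), unique(peaks_b$chrom))
  ga <- peaks_to_granges(peaks_a, lv)
  gb <- peaks_to_granges(peaks_b, lv)
  hits <- GenomicRanges::countOverlaps(ga, gb, minoverlap = min_bp)
  n_over <- sum(hits > 0)
  ra <- GenomicRanges::reduce(ga)
  rb <- GenomicRanges::reduce(gb)
  inter_bp <- sum(IRanges::width(GenomicRanges::intersect(ra, rb)))
  union_bp <- sum(IRanges::width(GenomicRanges::union(ra, rb)))
  structure(list(n_A = nrow(peaks_a), n_B = nrow(peaks_b),
                 n_A_overlapping_B = n_over,
                 fraction_A_overlapping = n_over / nrow(peaks_a),
                 percent_A_overlapping = round(100 * n_over / nrow(peaks_a)),
                 jaccard_bp = if (union_bp > 0) inter_bp / union_bp else NA_real_),
            class = "overlap_summary")
}

#' Enhancer and superenhancer colocalization counts
#'
#' Counts how many enhancer and superenhancer intervals are overlapped by
#' at least one peak; the superenhancer coverage is also given as a
#' percentage rounded to the nearest integer. With an empty superenhancer
#' set the percentage is not applicable (NA).
#'
#' @param peaks Peak set of the factor of interest.
#' @param enhancers,superenhancers [peak_set()] objects.
#' @return List with `n_enhancers`, `n_enhancers_cobound`,
#'   `n_superenhancers`, `n_SE_cobound`, `SE_fraction_percent`.
#' @export
superenhancer_colocalization <- function(peaks, enhancers, superenhancers) {
  lv <- unique(c(peaks$chrom, enhancers$chrom, superenhancers$chrom))
  gp <- peaks_to_granges(peaks, lv)
  n_enh <- GenomicRanges::countOverlaps(peaks_to_granges(enhancers, lv), gp)
  n_se_total <- nrow(superenhancers)
  n_se <- if (n_se_total > 0)
    sum(GenomicRanges::countOverlaps(peaks_to_granges(superenhancers, lv),
                                     gp) > 0)
  else 0L
  list(n_enhancers = nrow(enhancers),
       n_enhancers_cobound = sum(n_enh > 0),
       n_superenhancers = n_se_total,
       n_SE_cobound = n_se,
       SE_fraction_percent = if (n_se_total > 0)
         round(100 * n_se / n_se_total) else NA_real_)
}

#' Cross-method concordance of the top-N enriched peaks
#'
#' Ranks peaks by their primary enrichment (`rank_by`), takes the top N
#' (ties broken by chromosome then start, so the selection is
#' deterministic), and counts how many of them have a secondary enrichment
#' strictly below `fold_threshold` — peaks the second method failed to
#' recover.
#'
#' @param peaks [peak_set()] carrying both enrichment columns.
#' @param rank_by Name of the primary enrichment column.
#' @param secondary Name of the secondary enrichment column.
#' @param N Number of top peaks to consider (truncated with a warning when
#'   larger than the peak count).
#' @param fold_threshold Discordance threshold (strict `<`).
#' @return List of class `concordance_summary`: `N`, `fold_threshold`,
#'   `n_discordant`, `discordant_names`.
#' @export
top_n_concordance <- function(peaks, rank_by = "enrichment_A",
                              secondary = "enrichment_B", N = 10000,
                              fold_threshold = 2) {
  for (col in c(rank_by, secondary))
    if (is.null(peaks[[col]]) || anyNA(peaks[[col]]))
      stop("missing enrichment column: ", col)
  if (N > nrow(peaks)) {
    warning("N truncated to the number of peaks")
    N <- nrow(peaks)
  }
  ord <- order(-peaks[[rank_by]], peaks$chrom, peaks$start)
  top <- ord[seq_len(N)]
  disc <- top[peaks[[secondary]][top] < fold_threshold]
  structure(list(N = N, fold_threshold = fold_threshold,
                 n_discordant = length(disc),
                 discordant_names = peaks$name[disc]),
            class = "concordance_summary")
}

#' Differential occupancy between two conditions
#'
#' Per region: counts are normalized to counts-per-million with a
#' pseudocount of 1, log2-transformed, and compared between the two
#' conditions with a per-region t-test; p-values are BH-adjusted across
#' regions. By default the per-region variance is moderated (shrunk toward
#' the median variance across regions with a fixed 4-df prior), which is
#' essential for power at 2-3 replicates; `moderate_variance = FALSE`
#' gives a plain Welch test. A region is flagged preferential for a
#' condition when its adjusted p is strictly below `fdr` and its linear
#' fold change strictly above `min_fold` in that direction — the two
#' preferential flags are mutually exclusive by construction. Regions with
#' zero counts everywhere are left untested.
#'
#' @param counts Numeric matrix, regions x samples.
#' @param conditions Character vector (length = columns of `counts`) with
#'   exactly two distinct values; the first distinct value is reported as
#'   condition A. At least 2 replicates per condition.
#' @param fdr,min_fold Thresholds (both strict).
#' @param moderate_variance Use the moderated variance (default) or the
#'   plain Welch test.
#' @return Data frame of class `differential_occupancy`: per region
#'   `log2_fc` (A minus B), `p`, `adj_p`, `preferential`
#'   (`"A"`/`"B"`/`"none"`), `tested`.
#' @export
differential_occupancy <- function(counts, conditions, fdr = 0.05,
                                   min_fold = 1.5,
                                   moderate_variance = TRUE) {
  counts <- as.matrix(counts)
  lv <- unique(conditions)
  if (length(lv) != 2L) stop("exactly two conditions required")
  ia <- which(conditions == lv[1L])
  ib <- which(conditions == lv[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 replicates per condition")
  lcpm <- log2(t(t(counts) / colSums(counts) * 1e6) + 1)
  tested <- rowSums(counts) > 0
  wt <- welch_rows(lcpm[, ia, drop = FALSE], lcpm[, ib, drop = FALSE],
                   moderate = moderate_variance)
  lfc <- rowMeans(lcpm[, ia, drop = FALSE]) - rowMeans(lcpm[, ib, drop = FALSE])
  p <- wt$p
  p[!tested] <- NA
  adj <- rep(NA_real_, length(p))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  sig <- !is.na(adj) & adj < fdr & 2^abs(lfc) > min_fold
  pref <- ifelse(sig & lfc > 0, "A", ifelse(sig & lfc < 0, "B", "none"))
  out <- data.frame(region = rownames(counts), log2_fc = lfc, t = wt$t,
                    p = p, adj_p = adj, preferential = pref, tested = tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conditions") <- lv
  class(out) <- c("differential_occupancy", "data.frame")
  out
}

# vectorized two-group t-test over matrix rows. moderate = FALSE gives the
# plain Welch test. With moderation, the pooled per-row variance is shrunk
# toward the median variance across rows with a fixed prior weight of
# `prior_df` degrees of freedom and the t df grows accordingly — at 2-3
# replicates per group the raw variance estimate is too unstable for
# per-row testing under multiple-testing correction.
welch_rows <- function(a, b, moderate = FALSE, prior_df = 4) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (moderate) {
    df0 <- na + nb - 2
    vp <- (va * (na - 1) + vb * (nb - 1)) / df0
    v0 <- stats::median(vp)
    vmod <- (prior_df * v0 + df0 * vp) / (prior_df + df0)
    se2 <- vmod * (1 / na + 1 / nb)
    df <- rep(df0 + prior_df, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero standard error
  zero <- se2 == 0
  t[zero & ma == mb] <- 0
  p[zero & ma == mb] <- 1
  t[zero & ma != mb] <- sign(ma - mb)[zero & ma != mb] * Inf
  p[zero & ma != mb] <- .Machine$double.xmin
  list(t = t, p = p, df = df)
}

#' Assign genes to nearby peaks by TSS distance
#'
#' A gene is near a peak when the distance between its TSS and the nearest
#' covered base of the peak is strictly below `max_distance`. With 0-based
#' half-open peaks the last covered base is `end - 1`, so
#' `distance = max(0, start - tss, tss - (end - 1))`; a TSS inside the peak
#' has distance 0. Strand is ignored (the TSS position already encodes it).
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_annotation()].
#' @param max_distance Distance threshold in bp (strict `<`).
#' @return List with `pairs` (data frame `peak`, `gene_id`, `distance`),
#'   `peak_to_genes` and `gene_to_peaks` (named lists of character
#'   vectors).
#' @export
assign_nearby_genes <- function(peaks, genes, max_distance = 10000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_annotation"))
  pairs <- NULL
  for (ch in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    d <- pmax(pmax(outer(p$start, g$tss, "-"),
                   outer(-(p$end - 1L), g$tss, function(a, b) a + b)),
              0L)
    hit <- which(d < max_distance, arr.ind = TRUE)
    if (nrow(hit))
      pairs <- rbind(pairs, data.frame(
        peak = p$name[hit[, 1L]], gene_id = g$gene_id[hit[, 2L]],
        distance = d[hit], stringsAsFactors = FALSE))
  }
  if (is.null(pairs))
    pairs <- data.frame(peak = character(), gene_id = character(),
                        distance = integer(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$peak, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       peak_to_genes = split(pairs$gene_id, pairs$peak),
       gene_to_peaks = split(pairs$peak, pairs$gene_id))
}
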