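#' Differential expression after a knockdown
#'
#' Normalizes counts to counts-per-million with a pseudocount of 1,
#' log2-transforms, tests each gene between the knockdown condition and
#' the reference with a per-gene t-test, and adjusts p-values across genes
#' by Benjamini-Hochberg. By default the per-gene variance is moderated
#' (shrunk toward the median variance across genes with a fixed 4-df
#' prior); with 2-3 replicates the raw per-gene variance is too unstable
#' for a multiple-testing-corrected call, so this is the recommended mode.
#' `moderate_variance = FALSE` gives a plain Welch test. A gene is
#' differentially expressed when its adjusted p is strictly below `fdr`
#' and its linear fold change strictly above `min_fold` in either
#' direction. Genes with zero counts in all samples of both groups are
#' left untested.
#'
#' @param cm A [count_matrix()].
#' @param condition Condition label of the knockdown group.
#' @param reference Condition label of the reference group.
#' @param fdr,min_fold DE thresholds (both strict).
#' @param moderate_variance Use the moderated variance (default) or the
#'   plain Welch test.
#' @return Data frame of class `de_result`: per gene `log2_fc`
#'   (knockdown minus reference), `t`, `p`, `adj_p`, `de`, `tested`.
#' @export
de_test <- function(cm, condition, reference = "control", fdr = 0.01,
                    min_fold = 1.5, moderate_variance = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  ik <- which(cm$design$condition == condition)
  ir <- which(cm$design$condition == reference)
  if (length(ik) < 2L || length(ir) < 2L)
    stop("need >= 2 replicates per group")
  counts <- cm$counts[, c(ik, ir), drop = FALSE]
  lcpm <- log2(t(t(counts) / colSums(counts) * 1e6) + 1)
  ka <- seq_along(ik)
  kb <- length(ik) + seq_along(ir)
  tested <- rowSums(counts) > 0
  wt <- welch_rows(lcpm[, ka, drop = FALSE], lcpm[, kb, drop = FALSE],
                   moderate = moderate_variance)
  lfc <- rowMeans(lcpm[, ka, drop = FALSE]) - rowMeans(lcpm[, kb, drop = FALSE])
  p <- wt$p
  p[!tested] <- NA
  adj <- rep(NA_real_, length(p))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  de <- !is.na(adj) & adj < fdr & 2^abs(lfc) > min_fold
  out <- data.frame(gene_id = rownames(cm$counts), log2_fc = lfc, t = wt$t,
                    p = p, adj_p = adj, de = de, tested = tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  attr(out, "reference") <- reference
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify genetic interactions from single and double knockdowns
#'
#' For every gene differentially expressed in the single knockdown, the
#' interaction ratio is the double-knockdown log2 expression change divided
#' by the single-knockdown log2 change. A ratio inside the independence
#' band (inclusive) means the second factor does not modulate the effect;
#' below the band the effect is attenuated or sign-flipped (antagonistic,
#' the rescue pattern); above the band it is amplified (synergistic). The
#' log2 scale makes the ratio symmetric for up- and down-regulated targets,
#' and the DE fold filter guarantees a bounded-away-from-zero denominator.
#'
#' @param de_single [de_test()] result of the single knockdown; its DE set
#'   defines the target genes.
#' @param de_double [de_test()] result of the double knockdown (vs the same
#'   reference).
#' @param independence_band Inclusive ratio band classified as independent.
#' @return Data frame of class `gi_classification`: per target gene
#'   `delta_single`, `delta_double`, `ratio`, `class`.
#' @export
gi_classify <- function(de_single, de_double,
                        independence_band = c(0.5, 1.5)) {
  targets <- de_single$gene_id[de_single$de]
  idx <- match(targets, de_double$gene_id)
  if (anyNA(idx)) {
    warning(sprintf("skipping %d gene(s) missing from the double knockdown",
                    sum(is.na(idx))))
    targets <- targets[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  ds <- de_single$log2_fc[match(targets, de_single$gene_id)]
  dd <- de_double$log2_fc[idx]
  r <- dd / ds
  cls <- ifelse(r < independence_band[1L], "antagonistic",
                ifelse(r > independence_band[2L], "synergistic",
                       "independent"))
  out <- data.frame(gene_id = targets, delta_single = ds, delta_double = dd,
                    ratio = r, class = cls, stringsAsFactors = FALSE)
  class(out) <- c("gi_classification", "data.frame")
  out
}

#' Annotate a genetic-interaction classification with binding sites
#'
#' Flags each classified gene by whether it lies near a binding site of the
#' knocked-down factor (from [assign_nearby_genes()]) and tallies the
#' class x binding-site contingency counts.
#'
#' @param gi A [gi_classify()] result.
#' @param gene_peak_map The `gene_to_peaks` element of
#'   [assign_nearby_genes()] (named list: gene id -> peak names).
#' @return List with `table` (the annotated `gi` data frame, extra column
#'   `has_binding_site`) and `counts` (class x has_binding_site table).
#' @export
integrate_with_binding <- function(gi, gene_peak_map) {
  has_site <- gi$gene_id %in% names(gene_peak_map)[lengths(gene_peak_map) > 0]
  gi$has_binding_site <- has_site
  counts <- table(class = gi$class,
                  has_binding_site = factor(has_site, c(FALSE, TRUE)))
  list(table = gi, counts = counts)
}
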