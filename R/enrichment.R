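#' Enrichment filtering against a no-antibody control
#'
#' A protein counts as enriched when its signal-to-control fold change
#' exceeds `min_fold` (strictly) in every replicate pair. Replicates are
#' paired by their `replicate` index in the sample descriptors. A fold
#' change with zero control intensity and positive signal is `Inf` and
#' passes the filter: absence from the no-antibody control is the strongest
#' evidence of specificity. Proteins undetected in any bait replicate are
#' never enriched.
#'
#' Ranks are assigned over proteins detected in at least one bait sample,
#' in descending order of summed bait intensity, ties broken by protein id.
#'
#' @param table A [quant_table()].
#' @param bait_samples,control_samples Disjoint sets of sample labels.
#' @param min_fold Fold-change threshold (strict `>`).
#' @param require_all_replicates If `TRUE` (default) the threshold must be
#'   passed in every replicate pair; otherwise in at least one.
#' @return A data frame of class `enrichment_result` with one row per
#'   protein: per-replicate fold changes, `detected_all`, `enriched`,
#'   `abundance` (summed bait intensity) and `rank`.
#' @export
filter_enriched <- function(table, bait_samples, control_samples,
                            min_fold = 2, require_all_replicates = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  if (!length(bait_samples) || !length(control_samples))
    stop("bait and control sample sets must be non-empty")
  if (length(intersect(bait_samples, control_samples)))
    stop("bait and control sample sets must be disjoint")
  s <- table$samples
  bait <- s[match(bait_samples, s$label), , drop = FALSE]
  ctrl <- s[match(control_samples, s$label), , drop = FALSE]
  if (anyNA(bait$label) || anyNA(ctrl$label))
    stop("unknown sample label")
  pair <- match(bait$replicate, ctrl$replicate)
  if (anyNA(pair) || anyDuplicated(bait$replicate))
    stop("design error: bait and control replicates cannot be paired")
  bi <- table$intensity[, bait$label, drop = FALSE]
  ci <- table$intensity[, ctrl$label[pair], drop = FALSE]
  fold <- bi / ci
  fold[bi > 0 & ci == 0] <- Inf
  fold[bi == 0] <- NA  # undetected in that bait replicate
  pass <- fold > min_fold
  pass[is.na(pass)] <- FALSE
  detected_all <- rowSums(bi > 0) == ncol(bi)
  enriched <- detected_all &
    (if (require_all_replicates) rowSums(pass) == ncol(pass)
     else rowSums(pass) > 0)
  abundance <- rowSums(bi)
  out <- data.frame(protein_id = table$proteins$protein_id,
                    stringsAsFactors = FALSE)
  for (r in seq_len(ncol(fold)))
    out[[sprintf("fold_r%d", bait$replicate[r])]] <- fold[, r]
  out$detected_all <- detected_all
  out$enriched <- enriched
  out$abundance <- abundance
  out$rank <- NA_integer_
  det <- abundance > 0
  ord <- order(-abundance[det], out$protein_id[det])
  out$rank[which(det)[ord]] <- seq_len(sum(det))
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Rank proteins by estimated abundance
#'
#' Abundance is the sum of MS intensities across the named samples
#' (scale-equivalent to the mean under equal replicate counts and robust to
#' a missing replicate). Ranking is descending; ties are broken by protein
#' id so the order is deterministic. Proteins not detected in any of the
#' samples are dropped.
#'
#' @param table A [quant_table()].
#' @param samples Sample labels to sum over.
#' @return Data frame (`protein_id`, `abundance`, `rank`) ordered by rank.
#' @export
rank_by_abundance <- function(table, samples) {
  stopifnot(inherits(table, "quant_table"))
  if (!length(samples)) stop("samples must be non-empty")
  if (!all(samples %in% table$samples$label)) stop("unknown sample label")
  ab <- rowSums(table$intensity[, samples, drop = FALSE])
  det <- ab > 0
  ids <- table$proteins$protein_id[det]
  ab <- ab[det]
  ord <- order(-ab, ids)
  data.frame(protein_id = ids[ord], abundance = ab[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Bait and histone quality check on an abundance ranking
#'
#' A successful chromatin pull-down puts histones and the bait protein
#' itself among the most abundant proteins; this check reports their ranks
#' and an advisory pass flag (bait in the top `top_k` and at least one
#' histone in the top `top_k`). A missing bait yields an explicit
#' `"bait not detected"` status, never an error.
#'
#' @param ranked Ranking from [rank_by_abundance()].
#' @param bait_id Protein id of the bait.
#' @param histone_ids Protein ids annotated as histones.
#' @param top_k Rank cutoff for the pass flag.
#' @return List with `bait_rank`, `histone_ranks`, `pass` and `status`.
#' @export
bait_qc <- function(ranked, bait_id, histone_ids, top_k = 10) {
  if (!nrow(ranked)) stop("ranking is empty")
  bait_rank <- ranked$rank[match(bait_id, ranked$protein_id)]
  histone_ranks <- sort(ranked$rank[ranked$protein_id %in% histone_ids])
  if (is.na(bait_rank)) {
    return(list(bait_rank = NA_integer_, histone_ranks = histone_ranks,
                pass = FALSE, status = "bait not detected"))
  }
  pass <- bait_rank <= top_k && length(histone_ranks) &&
    histone_ranks[1L] <= top_k
  list(bait_rank = bait_rank, histone_ranks = histone_ranks,
       pass = isTRUE(pass),
       status = if (isTRUE(pass)) "pass" else
         sprintf("fail: bait rank %d", bait_rank))
}

#' Recovery and precision against a reference interactome
#'
#' Counts how many enriched proteins appear in a reference set and reports
#' the precision as a percentage of the method's detected proteins,
#' mirroring the usual "n of N detected (x%)" bookkeeping of interactome
#' benchmarks. The percentage is reported to one decimal.
#'
#' @param enriched_ids Protein ids called by the method.
#' @param reference_ids Reference interactor ids.
#' @param detected_count Number of proteins detected by the method (the
#'   precision denominator); must be >= the recovered count and > 0.
#' @return List with `n_recovered` and `precision_percent`.
#' @export
precision_against_reference <- function(enriched_ids, reference_ids,
                                        detected_count) {
  if (detected_count == 0) stop("undefined precision: detected_count is 0")
  n_recovered <- length(intersect(enriched_ids, reference_ids))
  if (detected_count < n_recovered)
    stop("detected_count must be >= the recovered count")
  list(n_recovered = n_recovered,
       precision_percent = round(100 * n_recovered / detected_count, 1))
}

#' Simple fold change
#'
#' @param after,before Positive quantities; `before` must be > 0.
#' @return `after / before`.
#' @export
fold_change <- function(after, before) {
  if (any(before == 0)) stop("division error: before is 0")
  after / before
}
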