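#' Compute replicate SILAC log2 ratios
#'
#' For each declared heavy/light sample pair, computes log2(heavy/light)
#' per protein. A pair with either channel at 0 (not detected) yields no
#' ratio (NA). By default ratios are median-centred per replicate, the
#' standard SILAC normalization for unequal channel loading.
#'
#' @param table A [quant_table()].
#' @param pairing Data frame with columns `replicate`, `heavy`, `light`
#'   naming the paired sample labels.
#' @param median_center Centre each replicate's ratios at median 0?
#' @return Matrix of log2 ratios, proteins x replicates (NA = no ratio).
#' @export
compute_ratios <- function(table, pairing, median_center = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  need <- c("replicate", "heavy", "light")
  if (!all(need %in% names(pairing)))
    stop("pairing needs columns replicate, heavy, light")
  labs <- table$samples$label
  if (!all(c(pairing$heavy, pairing$light) %in% labs))
    stop("pairing names unknown sample labels")
  h <- table$intensity[, pairing$heavy, drop = FALSE]
  l <- table$intensity[, pairing$light, drop = FALSE]
  r <- log2(h / l)
  r[h == 0 | l == 0] <- NA
  if (all(is.na(r))) stop("no valid heavy/light pairs produced any ratio")
  if (median_center) {
    med <- apply(r, 2L, stats::median, na.rm = TRUE)
    r <- sweep(r, 2L, med)
  }
  colnames(r) <- sprintf("rep%d", pairing$replicate)
  rownames(r) <- table$proteins$protein_id
  r
}

#' One-sample t-test of replicate log2 ratios against zero
#'
#' Tests, per protein, whether the mean replicate log2 ratio differs from
#' 0 (two-sided one-sample t), adjusts p-values across all tested proteins
#' by Benjamini-Hochberg, and flags significance at adjusted p <= `alpha`
#' (non-strict). Proteins with fewer than `min_replicates` ratios are left
#' untested. A protein with zero variance and nonzero mean has no finite t
#' statistic; its p-value is reported as the smallest representable double
#' and the row is flagged.
#'
#' @param ratios Matrix of log2 ratios (proteins x replicates, NA allowed).
#' @param alpha Significance level on the BH-adjusted p-value.
#' @param min_replicates Minimum number of ratios required to test.
#' @param moderate_variance Shrink each protein's variance halfway toward
#'   the median variance of all tested proteins (a fixed prior weight of
#'   one observed-variance worth) before computing t. Off by default: the
#'   plain t-test is the reference procedure.
#' @return Data frame of class `differential_result`: `protein_id`,
#'   `n_ratios`, `mean_log2_ratio`, `t`, `p`, `adj_p`, `significant`,
#'   `tested`, `zero_variance`.
#' @export
test_differential <- function(ratios, alpha = 0.1, min_replicates = 2,
                              moderate_variance = FALSE) {
  ratios <- as.matrix(ratios)
  n <- rowSums(!is.na(ratios))
  m <- rowMeans(ratios, na.rm = TRUE)
  v <- apply(ratios, 1L, stats::var, na.rm = TRUE)
  tested <- n >= min_replicates
  if (!any(tested)) stop("no protein has enough replicates to test")
  if (moderate_variance) {
    v0 <- stats::median(v[tested], na.rm = TRUE)
    # one pseudo-observation of the global variance per protein
    v <- (v * (n - 1) + v0) / n
  }
  se <- sqrt(v / n)
  tstat <- m / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zero_var <- tested & v == 0
  tstat[zero_var & m == 0] <- 0
  p[zero_var & m == 0] <- 1
  tstat[zero_var & m != 0] <- sign(m[zero_var & m != 0]) * Inf
  p[zero_var & m != 0] <- .Machine$double.xmin
  p[!tested] <- NA
  adj <- rep(NA_real_, length(p))
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(protein_id = rownames(ratios), n_ratios = n,
                    mean_log2_ratio = m, t = tstat, p = p, adj_p = adj,
                    significant = !is.na(adj) & adj <= alpha,
                    tested = tested, zero_variance = zero_var,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Intersect per-bait protein sets and subtract the control set
#'
#' Returns the proteins found in every set, with the no-antibody control
#' identifications removed.
#'
#' @param enriched_sets List of two or more character vectors of ids.
#' @param control_set Ids identified in the control (may be empty).
#' @return Character vector `(intersection of sets) \\ control_set`.
#' @export
subtract_control_and_intersect <- function(enriched_sets,
                                           control_set = character()) {
  if (length(enriched_sets) < 2L) stop("need at least two sets")
  setdiff(Reduce(intersect, enriched_sets), control_set)
}

#' Hierarchically cluster a protein x bait log2-ratio matrix
#'
#' Agglomerative clustering of both axes with average linkage. The default
#' distance is 1 - Pearson correlation; when a row or column is constant
#' (correlation undefined) the computation for that axis falls back to
#' Euclidean distance and the result is flagged. Missing cells are imputed
#' by 0 (no change) for clustering only, with the mask recorded.
#'
#' @param mat Numeric matrix of mean log2 ratios, proteins x baits.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List of class `ratio_clustering`: `row_hclust`, `col_hclust`,
#'   `matrix` (input, imputed, reordered by leaf order), `row_order`,
#'   `col_order`, `na_mask`, `fallback` (axes that fell back to Euclidean).
#' @export
cluster_ratio_matrix <- function(mat, distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two baits to cluster")
  na_mask <- is.na(mat)
  mat[na_mask] <- 0
  fallback <- character(0)
  dist_for <- function(m, axis) {
    if (distance == "correlation") {
      sds <- apply(m, 1L, stats::sd)
      if (any(sds == 0)) {
        fallback <<- c(fallback, axis)
        return(stats::dist(m))
      }
      return(stats::as.dist(1 - stats::cor(t(m))))
    }
    stats::dist(m)
  }
  row_h <- stats::hclust(dist_for(mat, "rows"), method = linkage)
  col_h <- stats::hclust(dist_for(t(mat), "cols"), method = linkage)
  list(row_hclust = row_h, col_hclust = col_h,
       matrix = mat[row_h$order, col_h$order, drop = FALSE],
       row_order = rownames(mat)[row_h$order],
       col_order = colnames(mat)[col_h$order],
       na_mask = na_mask, fallback = unique(fallback))
}

#' PTM-site ratio shifts relative to the parent protein
#'
#' Delta is the PTM-bearing peptide's mean log2 ratio minus the parent
#' protein's mean log2 ratio; modifications mostly follow their cognate
#' protein, and sites with |Delta| above the reporting threshold are
#' flagged as candidate stoichiometry shifts. Sites whose parent protein
#' has no ratio are skipped with a warning.
#'
#' @param ptm_ratios Data frame with columns `site_id`, `protein_id`,
#'   `ratio` (mean log2 ratio of the modified peptide).
#' @param protein_ratios Named numeric vector of parent-protein mean log2
#'   ratios.
#' @param flag_threshold |Delta| (log2 units) above which a site is flagged.
#' @return Data frame `site_id`, `protein_id`, `ptm_ratio`,
#'   `protein_ratio`, `delta`, `flagged`.
#' @export
ptm_shift <- function(ptm_ratios, protein_ratios, flag_threshold = 1) {
  ptm_ratios <- as.data.frame(ptm_ratios, stringsAsFactors = FALSE)
  parent <- protein_ratios[ptm_ratios$protein_id]
  orphan <- is.na(parent)
  if (any(orphan)) {
    warning(sprintf("skipping %d PTM site(s) with no parent protein ratio",
                    sum(orphan)))
  }
  keep <- !orphan
  delta <- ptm_ratios$ratio[keep] - parent[keep]
  data.frame(site_id = ptm_ratios$site_id[keep],
             protein_id = ptm_ratios$protein_id[keep],
             ptm_ratio = ptm_ratios$ratio[keep],
             protein_ratio = unname(parent[keep]),
             delta = unname(delta),
             flagged = abs(delta) > flag_threshold,
             stringsAsFactors = FALSE)
}
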