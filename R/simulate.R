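#' Method profile for the quant-experiment simulator
#'
#' Describes how strongly a (real or hypothetical) chromatin-proteomics
#' protocol enriches each protein class, on a multiplicative intensity
#' scale. A clean, chromatin-specific protocol has large factors for the
#' bait-specific classes and factors near 1 for the contaminant classes; a
#' sloppy protocol is emulated by raising the contaminant factors.
#'
#' @param class_factors Named positive numerics: intensity enrichment factor
#'   per annotation class. Classes absent from the vector fall back to 1.
#' @param bait_boost Positive factor applied to the bait protein itself
#'   (baits rank near the top of their own pull-down).
#' @param censor_limit Detection limit: simulated intensities below this
#'   value are recorded as 0 (not detected).
#' @param sigma_rep Standard deviation of the replicate noise on the log10
#'   intensity scale (0.15 ~ 40% CV, a typical MS replicate spread).
#' @param background Factor that the bait-specific classes (`bait`,
#'   `known_interactor`, `chromatin_dna_binder`, `histone`) are reset to in
#'   the no-antibody control.
#' @param mu_base Baseline log10 intensity of an unenriched protein.
#' @return An object of class `method_profile`.
#' @export
method_profile <- function(class_factors = c(known_interactor = 8, histone = 12,
                                             chromatin_dna_binder = 6,
                                             ribosomal = 1, ribonucleoprotein = 1,
                                             cytoplasmic_other = 1,
                                             affinity_reagent = 2),
                           bait_boost = 30, censor_limit = 1e4,
                           sigma_rep = 0.15, background = 1, mu_base = 6) {
  if (any(class_factors <= 0) || bait_boost <= 0 || background <= 0)
    stop("all enrichment factors must be > 0")
  if (sigma_rep < 0) stop("sigma_rep must be >= 0")
  structure(list(class_factors = class_factors, bait_boost = bait_boost,
                 censor_limit = censor_limit, sigma_rep = sigma_rep,
                 background = background, mu_base = mu_base),
            class = "method_profile")
}

# classes whose enrichment depends on the antibody; the no-antibody control
# sees them at background level only
specific_classes <- function() c("bait", "known_interactor",
                                 "chromatin_dna_binder", "histone")

#' Simulate a chromatin pull-down quantification experiment
#'
#' Draws per-protein log10 intensities from a lognormal model: baseline plus
#' the log10 class enrichment factor of the method profile, plus replicate
#' noise, censored at the detection limit. The bait protein gets the bait
#' boost. Optional no-antibody control samples are generated from the same
#' model with the bait-specific class factors reset to background, so the
#' planted signal-to-control fold change of a specific class equals
#' `factor / background`.
#'
#' @param n_proteins Total number of proteins, including the bait.
#' @param class_proportions Named proportions over the non-bait classes;
#'   must sum to 1 (tolerance 1e-9).
#' @param profile A [method_profile()].
#' @param n_replicates Number of pull-down replicates (>= 2).
#' @param include_control Also generate paired no-antibody control samples?
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with elements `table` ([quant_table()]), `catalog`
#'   ([annotation_catalog()]) and `truth` (data frame `protein_id`, `class`).
#' @export
simulate_quant_experiment <- function(n_proteins = 500,
                                      class_proportions = c(
                                        known_interactor = 0.08, histone = 0.04,
                                        chromatin_dna_binder = 0.12,
                                        ribosomal = 0.15,
                                        ribonucleoprotein = 0.15,
                                        cytoplasmic_other = 0.44,
                                        affinity_reagent = 0.02),
                                      profile = method_profile(),
                                      n_replicates = 2,
                                      include_control = TRUE, seed = NULL) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  ids <- sprintf("P%04d", seq_len(n_proteins))
  cls <- c("bait", rep(names(class_proportions),
                       apportion(n_proteins - 1L, class_proportions)))
  cls <- c(cls[1L], sample(cls[-1L]))  # shuffle non-bait assignment

  fac <- function(classes, control) {
    f <- profile$class_factors[classes]
    f[is.na(f)] <- 1
    f[classes == "bait"] <- profile$bait_boost
    if (control) f[classes %in% specific_classes()] <- profile$background
    unname(f)
  }

  draw <- function(control) {
    mu <- profile$mu_base + log10(fac(cls, control))
    m <- matrix(10^(mu + stats::rnorm(n_proteins * n_replicates,
                                      sd = profile$sigma_rep)),
                n_proteins, n_replicates)
    m[m < profile$censor_limit] <- 0
    m
  }

  bait <- draw(control = FALSE)
  intensity <- bait
  labels <- sprintf("bait_r%d", seq_len(n_replicates))
  cond <- rep("bait", n_replicates)
  if (include_control) {
    intensity <- cbind(intensity, draw(control = TRUE))
    labels <- c(labels, sprintf("ctrl_r%d", seq_len(n_replicates)))
    cond <- c(cond, rep("control", n_replicates))
  }
  rownames(intensity) <- ids
  colnames(intensity) <- labels
  # peptide count grows with intensity; deterministic given the intensity
  peptides <- matrix(ifelse(intensity > 0,
                            pmax(1, round(2 * (log10(pmax(intensity, 1)) - 3))),
                            0L), nrow(intensity), ncol(intensity),
                     dimnames = dimnames(intensity))
  samples <- data.frame(label = labels, channel = "none",
                        replicate = rep(seq_len(n_replicates),
                                        times = if (include_control) 2L else 1L),
                        condition = cond, stringsAsFactors = FALSE)
  tab <- quant_table(intensity, peptides, samples)
  catalog <- annotation_catalog(split(ids, cls))
  list(table = tab, catalog = catalog,
       truth = data.frame(protein_id = ids, class = cls,
                          stringsAsFactors = FALSE))
}

# split n into integer parts proportional to p (largest-remainder rounding)
apportion <- function(n, p) {
  q <- cumsum(p) / sum(p)
  diff(c(0L, round(q * n)))
}

#' Simulate SILAC heavy/light log2 ratios with planted differential proteins
#'
#' Replicate log2(heavy/light) ratios are drawn from Normal(effect, sigma)
#' where the planted effect is 0 for non-differential proteins and a signed
#' magnitude drawn uniformly from `effect_log2_range` for the
#' `n_differential` planted proteins. Heavy encodes the 2iL condition,
#' light the serum condition.
#'
#' @param n_proteins,n_differential Number of proteins and planted
#'   differential proteins (`n_differential <= n_proteins`).
#' @param effect_log2_range Range of planted |log2 effect| magnitudes.
#' @param sigma_rep Replicate noise sd on the log2 scale (>= 0).
#' @param n_replicates Number of replicate ratios per protein.
#' @param seed Integer seed.
#' @return List with `ratios` (matrix proteins x replicates) and `truth`
#'   (data frame `protein_id`, `differential`, `effect`).
#' @export
simulate_silac_ratios <- function(n_proteins = 500, n_differential = 50,
                                  effect_log2_range = c(2, 4),
                                  sigma_rep = 0.3, n_replicates = 3,
                                  seed = NULL) {
  if (n_differential > n_proteins)
    stop("n_differential must be <= n_proteins")
  if (sigma_rep < 0) stop("sigma_rep must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  effect <- numeric(n_proteins)
  idx <- if (n_differential > 0) sample(n_proteins, n_differential) else integer()
  if (length(idx))
    effect[idx] <- sample(c(-1, 1), n_differential, replace = TRUE) *
      stats::runif(n_differential, effect_log2_range[1L], effect_log2_range[2L])
  ratios <- matrix(stats::rnorm(n_proteins * n_replicates, mean = effect,
                                sd = sigma_rep),
                   n_proteins, n_replicates,
                   dimnames = list(ids, sprintf("rep%d", seq_len(n_replicates))))
  list(ratios = ratios,
       truth = data.frame(protein_id = ids,
                          differential = seq_len(n_proteins) %in% idx,
                          effect = effect, stringsAsFactors = FALSE))
}

#' Simulate genomic peak sets with an exact planted colocalization fraction
#'
#' Peaks are placed in non-adjacent slots on the declared chromosomes so
#' every planted overlap relation is exact: set B shares exactly
#' `round(colocalization_fraction * n_peaks_A)` intervals overlapping set A,
#' the remaining B peaks touch nothing, and the same fraction of the
#' superenhancer set is covered by an A peak while the rest is disjoint.
#' Each peak carries a lognormal enrichment value.
#'
#' @param genome_spec Named integer vector of chromosome lengths (bp).
#' @param n_peaks_A,n_peaks_B Peak counts for the two sets.
#' @param colocalization_fraction Fraction in \[0, 1\] of A peaks with an
#'   overlapping B partner (and of superenhancers covered by an A peak).
#' @param n_superenhancers Number of superenhancer intervals.
#' @param peak_width,se_width,pitch Width of peaks / superenhancers and the
#'   slot pitch; slots this far apart keep unrelated intervals > 10 kb from
#'   each other so proximity truths stay exact.
#' @param seed Integer seed.
#' @return List with `peaks_a`, `peaks_b`, `superenhancers` (all
#'   [peak_set()]) and `truth` (planted overlap bookkeeping, including the
#'   slot layout reused by [simulate_gene_annotation()]).
#' @export
simulate_peaks <- function(genome_spec = c(chr1 = 30e6, chr2 = 25e6),
                           n_peaks_A = 500, n_peaks_B = 500,
                           colocalization_fraction = 0.6,
                           n_superenhancers = 142,
                           peak_width = 1000, se_width = 8000, pitch = 25000,
                           seed = NULL) {
  if (colocalization_fraction < 0 || colocalization_fraction > 1)
    stop("colocalization_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_coloc <- round(colocalization_fraction * n_peaks_A)
  if (n_coloc > n_peaks_B)
    stop("generation error: set B too small to share ", n_coloc,
         " intervals with set A")
  n_se_coloc <- round(colocalization_fraction * n_superenhancers)
  n_slots <- n_peaks_A + (n_peaks_B - n_coloc) +
    (n_superenhancers - n_se_coloc)
  per_chrom <- floor(genome_spec / pitch)
  if (sum(per_chrom) < n_slots)
    stop("generation error: genome too small to fit the requested peaks ",
         "without violating start < end / disjointness")
  slots <- do.call(rbind, lapply(seq_along(genome_spec), function(i) {
    data.frame(chrom = names(genome_spec)[i],
               pos = as.integer((seq_len(per_chrom[i]) - 1L) * pitch),
               stringsAsFactors = FALSE)
  }))
  slots <- slots[seq_len(n_slots), , drop = FALSE]
  slots <- slots[sample(n_slots), , drop = FALSE]  # randomize placement

  take <- function(n) {
    out <- slots[seq_len(n), , drop = FALSE]
    slots <<- slots[-seq_len(n), , drop = FALSE]
    out
  }
  lognorm_enr <- function(n) round(stats::rlnorm(n, log(8), 0.8), 3)

  # set A: peak centered in its slot with small jitter
  sa <- take(n_peaks_A)
  a_start <- sa$pos + as.integer((pitch - peak_width) %/% 2L) +
    sample(-500:500, n_peaks_A, replace = TRUE)
  peaks_a <- peak_set(sa$chrom, a_start, a_start + peak_width,
                      name = sprintf("A_%04d", seq_len(n_peaks_A)),
                      enrichment = lognorm_enr(n_peaks_A))

  # colocalized B peaks: shifted copies of sampled A peaks (half overlap)
  idx_b <- if (n_coloc > 0) sort(sample(n_peaks_A, n_coloc)) else integer()
  b_chrom <- peaks_a$chrom[idx_b]
  b_start <- peaks_a$start[idx_b] + peak_width %/% 2L
  # disjoint B peaks in their own slots
  n_b_free <- n_peaks_B - n_coloc
  if (n_b_free > 0) {
    sb <- take(n_b_free)
    fs <- sb$pos + as.integer((pitch - peak_width) %/% 2L) +
      sample(-500:500, n_b_free, replace = TRUE)
    b_chrom <- c(b_chrom, sb$chrom)
    b_start <- c(b_start, fs)
  }
  peaks_b <- peak_set(b_chrom, b_start, b_start + peak_width,
                      name = sprintf("B_%04d", seq_len(n_peaks_B)),
                      enrichment = lognorm_enr(n_peaks_B))

  # superenhancers: covered ones wrap a sampled A peak, the rest are free
  idx_se <- if (n_se_coloc > 0) sort(sample(n_peaks_A, n_se_coloc)) else integer()
  se_chrom <- peaks_a$chrom[idx_se]
  se_start <- peaks_a$start[idx_se] - (se_width - peak_width) %/% 2L
  n_se_free <- n_superenhancers - n_se_coloc
  if (n_se_free > 0) {
    ss <- take(n_se_free)
    fs <- ss$pos + as.integer((pitch - se_width) %/% 2L)
    se_chrom <- c(se_chrom, ss$chrom)
    se_start <- c(se_start, fs)
  }
  ses <- peak_set(se_chrom, pmax(se_start, 0L), pmax(se_start, 0L) + se_width,
                  name = sprintf("SE_%04d", seq_len(n_superenhancers)))

  list(peaks_a = peaks_a, peaks_b = peaks_b, superenhancers = ses,
       truth = list(n_ab_overlap = n_coloc,
                    a_colocalized = peaks_a$name[idx_b],
                    n_se_covered = n_se_coloc,
                    se_covered = ses$name[seq_len(n_se_coloc)],
                    layout = list(pitch = pitch, peak_width = peak_width,
                                  genome_spec = genome_spec)))
}

#' Attach two enrichment columns with a planted discordant count
#'
#' Helper emulating a cross-method peak comparison: every peak gets a
#' primary (`enrichment_A`) and a secondary (`enrichment_B`) enrichment.
#' Exactly `n_discordant` peaks, sampled among the `top_n` by
#' `enrichment_A`, get a secondary enrichment strictly below
#' `fold_threshold`; all others sit strictly above it.
#'
#' @param peaks A [peak_set()].
#' @param n_discordant Planted number of discordant peaks.
#' @param top_n Size of the top set the discordant peaks are planted in.
#' @param fold_threshold Enrichment threshold separating the two groups.
#' @param seed Integer seed.
#' @return The peak set with `enrichment_A` / `enrichment_B` columns, plus a
#'   `truth` attribute listing the discordant peak names.
#' @export
simulate_concordant_enrichments <- function(peaks, n_discordant = 33,
                                            top_n = nrow(peaks),
                                            fold_threshold = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(peaks)
  top_n <- min(top_n, n)
  if (n_discordant > top_n) stop("n_discordant must be <= top_n")
  peaks$enrichment_A <- round(stats::rlnorm(n, log(10), 0.7), 4)
  ord <- order(-peaks$enrichment_A, peaks$chrom, peaks$start)
  disc <- sort(sample(ord[seq_len(top_n)], n_discordant))
  hi <- fold_threshold + round(stats::rlnorm(n, log(5), 0.6), 4)
  lo <- round(stats::runif(n, 0, fold_threshold * 0.95), 4)
  peaks$enrichment_B <- hi
  peaks$enrichment_B[disc] <- lo[disc]
  attr(peaks, "truth") <- list(discordant = peaks$name[disc])
  peaks
}

#' Simulate knockdown expression counts with planted genetic interactions
#'
#' Counts for four conditions (control, single knockdowns of the primary
#' and secondary factor, double knockdown) are drawn from a gamma-Poisson
#' (negative-binomial-like) model with one dispersion parameter. Target
#' genes carry a signed log2 effect in the primary single knockdown; their
#' double-knockdown effect is `r` times that, with `r = 1` for independent
#' genes, `r ~ U[0, 0.4]` for antagonistic and `r ~ U[1.6, 2.5]` for
#' synergistic genes, so the planted classes sit clearly outside the
#' classifier's default independence band.
#'
#' @param n_genes Number of genes.
#' @param baseline_log2_expr_range Range of baseline log2 mean counts.
#' @param n_targets Number of genes affected by the primary knockdown.
#' @param gi_label_proportions Named proportions over `independent`,
#'   `antagonistic`, `synergistic`; must sum to 1.
#' @param effect_log2 |log2| effect of the primary knockdown on its targets;
#'   values below `log2(1.5)` trigger a warning because such targets cannot
#'   pass the downstream DE fold filter.
#' @param dispersion Negative-binomial dispersion (0 = pure Poisson).
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @return List with `counts` ([count_matrix()]; conditions `control`,
#'   `kd_T`, `kd_P`, `kd_TP`) and `truth` (per-gene data frame with
#'   `is_target`, `delta_single`, `gi_label`, `ratio_r`).
#' @export
simulate_knockdown_counts <- function(n_genes = 2000,
                                      baseline_log2_expr_range = c(5, 12),
                                      n_targets = 200,
                                      gi_label_proportions = c(
                                        independent = 0.7,
                                        antagonistic = 0.15,
                                        synergistic = 0.15),
                                      effect_log2 = 2, dispersion = 0.05,
                                      n_replicates = 3, seed = NULL) {
  if (abs(sum(gi_label_proportions) - 1) > 1e-9)
    stop("gi_label_proportions must sum to 1")
  if (effect_log2 < log2(1.5))
    warning("effect_log2 < log2(1.5): targets cannot pass the DE fold filter")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("G%04d", seq_len(n_genes))
  base <- stats::runif(n_genes, baseline_log2_expr_range[1L],
                       baseline_log2_expr_range[2L])
  tgt <- sort(sample(n_genes, n_targets))
  labels <- rep("none", n_genes)
  lab_pool <- sample(rep(names(gi_label_proportions),
                         apportion(n_targets, gi_label_proportions)))
  labels[tgt] <- lab_pool
  delta <- numeric(n_genes)
  delta[tgt] <- sample(c(-1, 1), n_targets, replace = TRUE) * effect_log2
  r <- rep(NA_real_, n_genes)
  r[labels == "independent"] <- 1
  n_ant <- sum(labels == "antagonistic")
  r[labels == "antagonistic"] <- stats::runif(n_ant, 0, 0.4)
  n_syn <- sum(labels == "synergistic")
  r[labels == "synergistic"] <- stats::runif(n_syn, 1.6, 2.5)

  cond_delta <- cbind(control = 0, kd_T = delta, kd_P = 0,
                      kd_TP = ifelse(is.na(r), 0, r * delta))
  conds <- colnames(cond_delta)
  counts <- matrix(0L, n_genes, length(conds) * n_replicates)
  labs <- character(ncol(counts))
  j <- 0L
  for (cd in conds) {
    mu <- 2^(base + cond_delta[, cd])
    for (rep_i in seq_len(n_replicates)) {
      j <- j + 1L
      lambda <- if (dispersion > 0)
        stats::rgamma(n_genes, shape = 1 / dispersion,
                      scale = mu * dispersion)
      else mu
      counts[, j] <- stats::rpois(n_genes, lambda)
      labs[j] <- sprintf("%s_%d", cd, rep_i)
    }
  }
  dimnames(counts) <- list(ids, labs)
  design <- data.frame(sample = labs,
                       condition = rep(conds, each = n_replicates),
                       replicate = rep(seq_len(n_replicates), length(conds)),
                       stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, design),
       truth = data.frame(gene_id = ids, is_target = seq_len(n_genes) %in% tgt,
                          delta_single = delta, gi_label = labels,
                          ratio_r = r, stringsAsFactors = FALSE))
}

#' Simulate per-region occupancy counts for two conditions
#'
#' Gamma-Poisson counts per genomic region with a planted set of regions
#' preferentially occupied in the first condition at the stated fold.
#'
#' @param n_regions Number of regions.
#' @param n_preferential Planted regions with higher occupancy in
#'   `conditions[1]`.
#' @param fold Linear planted fold change of the preferential regions.
#' @param dispersion Negative-binomial dispersion.
#' @param n_replicates Replicates per condition.
#' @param conditions Character vector of the two condition names.
#' @param baseline_log2_range Range of baseline log2 mean counts.
#' @param seed Integer seed.
#' @return List with `counts` matrix (regions x samples), `conditions`
#'   vector aligned with the columns, and `truth` (preferential region ids).
#' @export
simulate_occupancy_counts <- function(n_regions = 1000, n_preferential = 50,
                                      fold = 4, dispersion = 0.05,
                                      n_replicates = 3,
                                      conditions = c("cond2iL", "serum"),
                                      baseline_log2_range = c(5, 10),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("region_%04d", seq_len(n_regions))
  base <- stats::runif(n_regions, baseline_log2_range[1L],
                       baseline_log2_range[2L])
  pref <- sort(sample(n_regions, n_preferential))
  delta <- numeric(n_regions)
  delta[pref] <- log2(fold)
  cols <- character(0)
  cond_of <- character(0)
  counts <- NULL
  for (k in 1:2) {
    mu <- 2^(base + if (k == 1) delta else 0)
    for (rep_i in seq_len(n_replicates)) {
      lambda <- if (dispersion > 0)
        stats::rgamma(n_regions, shape = 1 / dispersion,
                      scale = mu * dispersion)
      else mu
      counts <- cbind(counts, stats::rpois(n_regions, lambda))
      cols <- c(cols, sprintf("%s_%d", conditions[k], rep_i))
      cond_of <- c(cond_of, conditions[k])
    }
  }
  dimnames(counts) <- list(ids, cols)
  list(counts = counts, conditions = cond_of,
       truth = list(preferential = ids[pref], condition = conditions[1L]))
}

#' Simulate a gene annotation with a planted fraction of peak-proximal genes
#'
#' Uses the slot layout of [simulate_peaks()] so the planted proximity
#' relation is exact: "near" genes get a TSS 500-2000 bp upstream of a
#' sampled peak (well inside the 10 kb rule) and "far" genes sit at slot
#' boundaries, > 10 kb from every peak.
#'
#' @param peaks Peak set A from [simulate_peaks()].
#' @param layout The `truth$layout` element of the same [simulate_peaks()]
#'   call.
#' @param n_genes Number of genes.
#' @param fraction_near Fraction of genes planted near a peak.
#' @param seed Integer seed.
#' @return List with `genes` ([gene_annotation()]) and `truth` (character
#'   vector of gene ids planted near a peak).
#' @export
simulate_gene_annotation <- function(peaks, layout, n_genes = 300,
                                     fraction_near = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_near <- round(fraction_near * n_genes)
  if (n_near > nrow(peaks)) stop("not enough peaks to plant near genes")
  ids <- sprintf("G%04d", seq_len(n_genes))
  near_idx <- sort(sample(nrow(peaks), n_near))
  chrom <- peaks$chrom[near_idx]
  tss <- peaks$start[near_idx] - sample(500:2000, n_near, replace = TRUE)
  n_far <- n_genes - n_near
  if (n_far > 0) {
    # far genes at slot origins: >= ~11 kb from any centred peak
    pitch <- layout$pitch
    gs <- layout$genome_spec
    far_chrom <- character(0); far_pos <- integer(0)
    for (i in seq_along(gs)) {
      k <- floor(gs[i] / pitch)
      far_chrom <- c(far_chrom, rep(names(gs)[i], k))
      far_pos <- c(far_pos, as.integer((seq_len(k) - 1L) * pitch))
    }
    pick <- sample(length(far_pos), n_far)
    chrom <- c(chrom, far_chrom[pick])
    tss <- c(tss, far_pos[pick] + sample(0:300, n_far, replace = TRUE))
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  list(genes = gene_annotation(ids, chrom, pmax(tss, 0L), strand),
       truth = list(near = ids[seq_len(n_near)],
                    near_peak = peaks$name[near_idx]))
}
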