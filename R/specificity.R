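# class precedence used to resolve multi-class annotations into a partition
CLASS_PRECEDENCE <- c("bait", "known_interactor", "histone",
                      "chromatin_dna_binder", "ribosomal",
                      "ribonucleoprotein", "affinity_reagent",
                      "cytoplasmic_other")

# default potential-true/false-positive class groupings
PTP_CLASSES <- c("known_interactor", "histone", "chromatin_dna_binder")
PFP_CLASSES <- c("ribosomal", "ribonucleoprotein", "cytoplasmic_other")

#' Resolve a class catalog into an effective partition
#'
#' A protein may be annotated in several classes (a known interactor can
#' also be a chromatin binder); the stacked intensity-fraction report needs
#' disjoint classes, so each annotated protein is assigned exactly one
#' effective class by precedence: bait > known_interactor > histone >
#' chromatin_dna_binder > ribosomal > ribonucleoprotein > affinity_reagent >
#' cytoplasmic_other, followed by any non-reserved classes in catalog
#' order. Proteins absent from the catalog are later treated as
#' `unclassified`.
#'
#' @param catalog An [annotation_catalog()].
#' @return Named character vector mapping protein id to effective class.
#' @export
resolve_classes <- function(catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  order_names <- c(intersect(CLASS_PRECEDENCE, names(catalog)),
                   setdiff(names(catalog), CLASS_PRECEDENCE))
  assignment <- character(0)
  for (nm in order_names) {
    new <- setdiff(catalog[[nm]], names(assignment))
    if (length(new))
      assignment[new] <- nm
  }
  assignment
}

#' Per-class intensity fractions and the PTP/PFP specificity ratio
#'
#' Sums the MS intensities of each effective class over the named samples
#' and normalizes by the total protein intensity of the same samples.
#' Proteins not in the partition contribute to the total as `unclassified`.
#' The specificity ratio is the summed fraction of the potential true
#' positive classes divided by that of the potential false positive
#' classes; it is invariant under uniform intensity rescaling.
#'
#' @param table A [quant_table()].
#' @param partition Named class assignment from [resolve_classes()].
#' @param samples Sample labels to sum over.
#' @return A list of class `specificity_report`: `fractions` (data frame
#'   `class`, `intensity`, `fraction`), `ptp_fraction`, `pfp_fraction` and
#'   `specificity_ratio`.
#' @export
class_intensity_fractions <- function(table, partition, samples) {
  stopifnot(inherits(table, "quant_table"))
  if (!length(samples)) stop("samples must be non-empty")
  ab <- rowSums(table$intensity[, samples, drop = FALSE])
  total <- sum(ab)
  if (total <= 0) stop("undefined fractions: zero total intensity")
  cls <- partition[table$proteins$protein_id]
  cls[is.na(cls)] <- "unclassified"
  sums <- tapply(ab, cls, sum)
  fr <- data.frame(class = names(sums), intensity = as.numeric(sums),
                   fraction = as.numeric(sums) / total,
                   stringsAsFactors = FALSE)
  rep <- list(fractions = fr,
              ptp_fraction = sum(fr$fraction[fr$class %in% PTP_CLASSES]),
              pfp_fraction = sum(fr$fraction[fr$class %in% PFP_CLASSES]))
  rep$specificity_ratio <- specificity_ratio(rep)
  class(rep) <- "specificity_report"
  rep
}

#' PTP/PFP intensity-fraction specificity ratio
#'
#' @param report A `specificity_report` (or any list with a `fractions`
#'   data frame).
#' @param ptp_classes,pfp_classes Class names making up the potential true
#'   and false positive groups.
#' @return The ratio of summed PTP to summed PFP fractions; `Inf` when the
#'   PFP sum is 0 and the PTP sum positive.
#' @export
specificity_ratio <- function(report, ptp_classes = PTP_CLASSES,
                              pfp_classes = PFP_CLASSES) {
  fr <- report$fractions
  ptp <- sum(fr$fraction[fr$class %in% ptp_classes])
  pfp <- sum(fr$fraction[fr$class %in% pfp_classes])
  if (ptp == 0 && pfp == 0) stop("undefined ratio: both class sums are 0")
  if (pfp == 0) return(Inf)
  ptp / pfp
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("specificity_report\n")
  print(x$fractions, row.names = FALSE)
  cat(sprintf("PTP %.3f / PFP %.3f, specificity ratio %.2f\n",
              x$ptp_fraction, x$pfp_fraction, x$specificity_ratio))
  invisible(x)
}

#' Cumulative class membership along an abundance ranking
#'
#' For a given class, counts how many of the top-x ranked proteins belong
#' to it, for x = 1..n. `y_fraction` normalizes by the class size among the
#' ranked proteins; for a class with no detected members the count curve is
#' flat zero and `y_fraction` is undefined (NA), reported with
#' `class_size = 0`.
#'
#' @param ranked Ranking from [rank_by_abundance()] (or any data frame with
#'   `protein_id` in rank order).
#' @param partition Named class assignment.
#' @param class_name Class to trace.
#' @return A data frame of class `cumulative_class_curve` with columns
#'   `rank`, `y_count`, `y_fraction`; attribute `class_size`.
#' @export
cumulative_class_curve <- function(ranked, partition, class_name) {
  known <- unique(c(partition, CLASS_PRECEDENCE, "unclassified"))
  if (!class_name %in% known)
    stop("unknown class: ", class_name)
  cls <- partition[ranked$protein_id]
  cls[is.na(cls)] <- "unclassified"
  member <- cls == class_name
  y <- cumsum(member)
  size <- sum(member)
  out <- data.frame(rank = seq_along(y), y_count = y,
                    y_fraction = if (size > 0) y / size else NA_real_)
  attr(out, "class_size") <- size
  attr(out, "class_name") <- class_name
  class(out) <- c("cumulative_class_curve", "data.frame")
  out
}

#' Affinity-reagent contamination accounting
#'
#' Sums the intensity and peptide counts attributed to affinity-reagent
#' proteins (immunoglobulin chains, protein A) over the named samples, and
#' expresses both as fractions of the totals. Large values flag a protocol
#' whose washes fail to remove the IP antibody and bead proteins.
#'
#' @param table A [quant_table()].
#' @param partition Named class assignment (class `affinity_reagent`).
#' @param samples Sample labels to sum over.
#' @return List of class `contamination_report` with `intensity`,
#'   `intensity_fraction`, `peptides`, `peptide_fraction`.
#' @export
contamination_report <- function(table, partition, samples) {
  stopifnot(inherits(table, "quant_table"))
  ab <- rowSums(table$intensity[, samples, drop = FALSE])
  pep <- rowSums(table$peptides[, samples, drop = FALSE])
  cls <- partition[table$proteins$protein_id]
  is_reagent <- !is.na(cls) & cls == "affinity_reagent"
  total_ab <- sum(ab)
  total_pep <- sum(pep)
  structure(list(
    intensity = sum(ab[is_reagent]),
    intensity_fraction = if (total_ab > 0) sum(ab[is_reagent]) / total_ab else 0,
    peptides = sum(pep[is_reagent]),
    peptide_fraction = if (total_pep > 0) sum(pep[is_reagent]) / total_pep else 0
  ), class = "contamination_report")
}
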