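#' Protein quantification table
#'
#' Container for per-protein MS intensities and peptide counts across a set
#' of described samples. Intensity 0 encodes "not detected"; there is no NA
#' sentinel. A peptide count of 0 implies intensity 0.
#'
#' @param intensity Numeric matrix, proteins x samples, rownames are protein
#'   ids, colnames are sample labels. All values must be finite and >= 0.
#' @param peptides Integer matrix of per-sample peptide counts with the same
#'   dimensions as `intensity`. If `NULL`, presence/absence counts
#'   (`intensity > 0`) are used.
#' @param samples Data frame of sample descriptors with columns `label`,
#'   `channel` (one of `"light"`, `"heavy"`, `"none"`), `replicate`
#'   (integer >= 1) and `condition`. Row order must match the columns of
#'   `intensity`.
#' @param gene_symbol Optional character vector of gene symbols, one per
#'   protein. Defaults to the protein ids.
#'
#' @return An object of class `quant_table`: a list with elements
#'   `intensity`, `peptides`, `samples` and `proteins`.
#' @export
quant_table <- function(intensity, peptides = NULL, samples, gene_symbol = NULL) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) < 1L || ncol(intensity) < 1L)
    stop("quant_table needs at least one protein and one sample")
  ids <- rownames(intensity)
  if (is.null(ids)) stop("intensity matrix must carry protein ids as rownames")
  if (anyDuplicated(ids))
    stop("duplicate protein_id: ", ids[duplicated(ids)][1L])
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (is.null(peptides)) {
    peptides <- matrix(as.integer(intensity > 0), nrow(intensity),
                       ncol(intensity), dimnames = dimnames(intensity))
  }
  peptides <- as.matrix(peptides)
  storage.mode(peptides) <- "integer"
  if (!identical(dim(peptides), dim(intensity)))
    stop("peptide count matrix must match the intensity matrix dimensions")
  if (any(peptides < 0)) stop("peptide counts must be >= 0")
  if (any(peptides == 0 & intensity > 0))
    stop("peptide_count = 0 implies intensity = 0; violated for ",
         ids[which(rowSums(peptides == 0 & intensity > 0) > 0)[1L]])
  samples <- validate_samples(samples)
  if (nrow(samples) != ncol(intensity))
    stop("sample descriptors do not match the intensity columns")
  if (!is.null(colnames(intensity)) &&
      !identical(colnames(intensity), samples$label))
    stop("intensity column names disagree with sample labels")
  colnames(intensity) <- colnames(peptides) <- samples$label
  if (is.null(gene_symbol)) gene_symbol <- ids
  structure(list(
    intensity = intensity,
    peptides  = peptides,
    samples   = samples,
    proteins  = data.frame(protein_id = ids, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE)
  ), class = "quant_table")
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("label", "channel", "replicate", "condition")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample descriptors lack columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$label))
    stop("duplicate sample label: ",
         samples$label[duplicated(samples$label)][1L])
  if (!all(samples$channel %in% c("light", "heavy", "none")))
    stop("channel must be one of light/heavy/none")
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop("replicate indices must be integers >= 1")
  rownames(samples) <- NULL
  samples[need]
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensity)

#' Named protein class catalog
#'
#' A catalog maps class names to sets of protein ids (GMT-style). Reserved
#' class names used by the specificity scoring are `bait`, `histone`,
#' `known_interactor`, `chromatin_dna_binder`, `ribosomal`,
#' `ribonucleoprotein`, `cytoplasmic_other` and `affinity_reagent`; any
#' other class names are carried along untouched.
#'
#' @param classes Named list of character vectors of protein ids.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(classes = list()) {
  if (length(classes)) {
    nm <- names(classes)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("every class must have a non-empty name")
    classes <- lapply(classes, function(v) unique(as.character(v)))
  }
  structure(classes, class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d classes\n", length(x)))
  for (nm in names(x)) cat(sprintf("  %s: %d proteins\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Genomic peak set
#'
#' Intervals are 0-based half-open `[start, end)` throughout; any 1-based
#' input must be converted by the caller. Column `enrichment` is an optional
#' non-negative real per peak; further columns are preserved.
#'
#' @param chrom,start,end,name Vectors defining the intervals; `name`
#'   defaults to `peak_<i>`.
#' @param enrichment Optional numeric vector of enrichment values (>= 0).
#' @param ... Further per-peak columns (recycled by `data.frame`).
#' @return A `data.frame` with class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, enrichment = NULL, ...) {
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (!is.null(enrichment)) df$enrichment <- as.numeric(enrichment)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_peak_set(df)
}

validate_peak_set <- function(df) {
  if (any(is.na(df$chrom)) || any(is.na(df$start)) || any(is.na(df$end)))
    stop("NA in required peak columns")
  if (any(df$start < 0)) stop("peak start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("interval with start >= end at record %d (%s:%d-%d)",
                 bad[1L], df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]))
  if (!is.null(df$enrichment) && any(df$enrichment < 0, na.rm = TRUE))
    stop("enrichment must be >= 0")
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Gene annotation (TSS table)
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param tss 0-based transcription start positions (>= 0).
#' @param strand `"+"` or `"-"`; used only to locate the TSS, peak proximity
#'   itself is strand-agnostic.
#' @return A `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = "+") {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = as.integer(tss),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  if (any(df$tss < 0)) stop("tss must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Expression count matrix with a knockdown design
#'
#' @param counts Integer matrix, genes x samples, with gene ids as rownames.
#' @param design Data frame with columns `sample`, `condition`, `replicate`
#'   describing the columns of `counts` in order.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `design`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene_id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(design) != ncol(counts))
    stop("design rows must match count columns")
  if (!is.null(colnames(counts)) && !identical(colnames(counts), design$sample))
    stop("count column names disagree with design samples")
  if (any(table(design$condition) < 1L)) stop("condition with no samples")
  colnames(counts) <- design$sample
  design$replicate <- as.integer(design$replicate)
  rownames(design) <- NULL
  structure(list(counts = counts, design = design[need]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
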