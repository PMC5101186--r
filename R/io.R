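#' Read a protein quantification table from TSV
#'
#' The on-disk dialect is a plain TSV with a header: a `protein_id` column,
#' an optional `gene_symbol` column, one `intensity.<label>` column per
#' sample and (optionally) one `peptides.<label>` column per sample. The
#' sample descriptors travel in a sidecar table (see [read_sample_spec()])
#' rather than being squeezed into column names.
#'
#' Missing intensity cells are read as 0 (not detected). Duplicate protein
#' ids, negative intensities and absent sample columns are rejected with the
#' offending line identified.
#'
#' @param path Path to the TSV file.
#' @param sample_spec Data frame of sample descriptors (`label`, `channel`,
#'   `replicate`, `condition`).
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, sample_spec) {
  df <- read_tsv_checked(path)
  if (!"protein_id" %in% names(df))
    stop("malformed header in ", path, ": no protein_id column")
  spec <- validate_samples(sample_spec)
  dup <- which(duplicated(df$protein_id))
  if (length(dup))
    stop(sprintf("duplicate protein_id '%s' at line %d of %s",
                 df$protein_id[dup[1L]], dup[1L] + 1L, path))
  icols <- paste0("intensity.", spec$label)
  miss <- setdiff(icols, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  intensity <- as.matrix(df[icols])
  intensity[is.na(intensity)] <- 0
  neg <- which(intensity < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity at line %d of %s", neg[1L, 1L] + 1L, path))
  pcols <- paste0("peptides.", spec$label)
  peptides <- NULL
  if (all(pcols %in% names(df))) {
    peptides <- as.matrix(df[pcols])
    peptides[is.na(peptides)] <- 0L
  }
  rownames(intensity) <- df$protein_id
  if (!is.null(peptides)) rownames(peptides) <- df$protein_id
  colnames(intensity) <- spec$label
  if (!is.null(peptides)) colnames(peptides) <- spec$label
  gene_symbol <- if ("gene_symbol" %in% names(df)) df$gene_symbol else NULL
  quant_table(intensity, peptides, spec, gene_symbol)
}

#' Write a protein quantification table to TSV
#'
#' Inverse of [read_quant_table()]; numeric cells are written with enough
#' digits that a read/write cycle reproduces the table exactly.
#'
#' @param x A [quant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  out <- data.frame(protein_id = x$proteins$protein_id,
                    gene_symbol = x$proteins$gene_symbol,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x$samples))) {
    out[[paste0("intensity.", x$samples$label[i])]] <-
      num_chr(x$intensity[, i])
    out[[paste0("peptides.", x$samples$label[i])]] <- x$peptides[, i]
  }
  write_tsv(out, path)
}

#' Read / write sample descriptors
#'
#' The sidecar sample table is a TSV with columns `label`, `channel`,
#' `replicate`, `condition`.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame of sample descriptors.
#' @export
read_sample_spec <- function(path) {
  validate_samples(read_tsv_checked(path))
}

#' @rdname read_sample_spec
#' @param spec Sample descriptor data frame.
#' @export
write_sample_spec <- function(spec, path) {
  write_tsv(validate_samples(spec), path)
}

#' Read a protein class catalog (GMT-like)
#'
#' One class per line: class name, a description field (ignored, `.` by
#' convention), then tab-separated protein ids.
#'
#' @param path Path to the catalog file.
#' @return An [annotation_catalog()].
#' @export
read_annotation_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  classes <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!nzchar(parts[1L]))
      stop(sprintf("empty class name at line %d of %s", i, path))
    ids <- if (length(parts) > 2L) parts[-(1:2)] else character()
    classes[[parts[1L]]] <- ids[nzchar(ids)]
  }
  annotation_catalog(classes)
}

#' @rdname read_annotation_catalog
#' @param catalog An [annotation_catalog()].
#' @export
write_annotation_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  lines <- vapply(names(catalog), function(nm) {
    paste(c(nm, ".", catalog[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED3+ file
#'
#' Tab-separated, no header, at least three columns (`chrom`, `start`,
#' `end`), 0-based half-open. Column 4 is the peak name, column 5 an
#' optional real-valued enrichment, further numeric columns are kept as
#' `extra1`, `extra2`, ...
#'
#' @param path Path to the BED file.
#' @return A [peak_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop(sprintf("fewer than 3 columns at line %d of %s",
                 which(ncols < 3L)[1L], path))
  k <- min(ncols)
  mat <- t(vapply(parts, function(p) p[seq_len(k)], character(k)))
  if (k == 3L) mat <- matrix(mat, ncol = 3L)
  start <- suppressWarnings(as.integer(mat[, 2L]))
  end <- suppressWarnings(as.integer(mat[, 3L]))
  if (any(is.na(start)) || any(is.na(end)))
    stop(sprintf("non-integer coordinate at line %d of %s",
                 which(is.na(start) | is.na(end))[1L], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("start >= end at line %d of %s", bad[1L], path))
  df <- data.frame(chrom = mat[, 1L], start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (k >= 4L) mat[, 4L] else sprintf("peak_%d", seq_len(nrow(df)))
  if (k >= 5L) df$enrichment <- as.numeric(mat[, 5L])
  if (k >= 6L) for (j in 6:k) df[[paste0("extra", j - 5L)]] <-
      as.numeric(mat[, j])
  validate_peak_set(df)
}

#' @rdname read_bed
#' @param peaks A [peak_set()].
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  cols <- list(peaks$chrom, peaks$start, peaks$end, peaks$name)
  extra <- setdiff(names(peaks), c("chrom", "start", "end", "name"))
  for (nm in extra) cols <- c(cols, list(num_chr(peaks[[nm]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' TSV with header and columns `gene_id`, `chrom`, `tss`, `strand`.
#'
#' @param path Path to the TSV file.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_checked(path)
  gene_annotation(df$gene_id, df$chrom, df$tss, df$strand)
}

#' @rdname read_gene_annotation
#' @param genes A [gene_annotation()].
#' @export
write_gene_annotation <- function(genes, path) {
  stopifnot(inherits(genes, "gene_annotation"))
  write_tsv(as.data.frame(genes), path)
}

#' Read an expression count matrix from TSV
#'
#' TSV with a header: `gene_id` column followed by one integer column per
#' sample. The design travels in a sidecar table (columns `sample`,
#' `condition`, `replicate`) mapping the count columns to conditions.
#'
#' @param path Path to the counts TSV.
#' @param design Data frame assigning `condition` and `replicate` to each
#'   `sample` column.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design) {
  df <- read_tsv_checked(path)
  if (!"gene_id" %in% names(df))
    stop("malformed header in ", path, ": no gene_id column")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  miss <- setdiff(design$sample, names(df))
  if (length(miss))
    stop("design error: sample column(s) absent from ", path, ": ",
         paste(miss, collapse = ", "))
  counts <- as.matrix(df[design$sample])
  nonint <- which(is.na(counts) | counts != round(counts), arr.ind = TRUE)
  if (nrow(nonint))
    stop(sprintf("non-integer count at line %d, column '%s' of %s",
                 nonint[1L, 1L] + 1L, design$sample[nonint[1L, 2L]], path))
  rownames(counts) <- df$gene_id
  count_matrix(counts, design)
}

#' @rdname read_counts
#' @param x A [count_matrix()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  out <- data.frame(gene_id = rownames(x$counts), stringsAsFactors = FALSE)
  for (i in seq_len(ncol(x$counts)))
    out[[x$design$sample[i]]] <- x$counts[, i]
  write_tsv(out, path)
}

#' @rdname read_counts
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sample", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df[need]
}

#' @rdname read_counts
#' @export
write_design <- function(design, path) {
  write_tsv(as.data.frame(design), path)
}

# internal TSV helpers ------------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# full-precision numeric formatting so write/read cycles are bit-stable
num_chr <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else x
}
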