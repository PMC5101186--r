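#' Run the multi-method benchmark
#'
#' Executes the enrichment filter, abundance ranking, bait quality check,
#' class intensity fractions, specificity ratio, contamination accounting
#' and (optionally) reference precision for each configured method, and
#' consolidates one row per method plus a cross-method ordering by
#' specificity ratio. A failing method is recorded in the report and does
#' not abort the others.
#'
#' @param config List with elements:
#'   * `methods`: list of method entries; each entry has `name`, either
#'     `table` (a [quant_table()]) or `quant_path` + `sample_spec_path`,
#'     `bait_samples`, `control_samples`, and optionally `catalog` (an
#'     [annotation_catalog()] or a path, overriding the shared one),
#'     `bait_id`, `histone_ids`, `reference_ids`, `detected_count`.
#'   * `catalog`: shared [annotation_catalog()] or path to a GMT-like file.
#'   * `min_fold`: enrichment threshold (default 2).
#' @param outdir Optional directory for per-method TSVs and the
#'   consolidated report (TSV + JSON).
#' @return List of class `benchmark_report`: `report` (one data frame row
#'   per method), `ordering` (method names by decreasing specificity
#'   ratio), `details` (per-method stage outputs), `n_failed`.
#' @export
run_benchmark <- function(config, outdir = NULL) {
  if (is.null(config$methods) || !length(config$methods))
    stop("usage error: config lists no methods")
  min_fold <- config$min_fold %||% 2
  shared_catalog <- load_catalog(config$catalog)
  rows <- list()
  details <- list()
  for (m in config$methods) {
    res <- tryCatch(
      benchmark_one(m, shared_catalog, min_fold),
      error = function(e) list(row = data.frame(
        method = m$name, failed = TRUE, error = conditionMessage(e),
        n_detected = NA, n_enriched = NA, bait_qc = NA,
        ptp_fraction = NA, pfp_fraction = NA, specificity_ratio = NA,
        contamination_intensity_fraction = NA,
        contamination_peptide_fraction = NA,
        n_recovered = NA, precision_percent = NA,
        stringsAsFactors = FALSE), detail = NULL))
    rows[[m$name]] <- res$row
    details[[m$name]] <- res$detail
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ok <- !report$failed & !is.na(report$specificity_ratio)
  ordering <- report$method[ok][order(-report$specificity_ratio[ok])]
  out <- structure(list(report = report, ordering = ordering,
                        details = details, n_failed = sum(report$failed)),
                   class = "benchmark_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report, file.path(outdir, "benchmark_report.tsv"))
    jsonlite::write_json(
      list(ordering = ordering,
           methods = lapply(seq_len(nrow(report)), function(i)
             as.list(report[i, ]))),
      file.path(outdir, "benchmark_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(details)) {
      if (!is.null(details[[nm]]))
        write_tsv(details[[nm]]$enrichment,
                  file.path(outdir, sprintf("enrichment_%s.tsv", nm)))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_catalog <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "annotation_catalog")) return(x)
  read_annotation_catalog(x)
}

benchmark_one <- function(m, shared_catalog, min_fold) {
  tab <- if (!is.null(m$table)) m$table
  else read_quant_table(m$quant_path, read_sample_spec(m$sample_spec_path))
  catalog <- load_catalog(m$catalog) %||% shared_catalog
  if (is.null(catalog)) stop("no annotation catalog for method ", m$name)
  enr <- filter_enriched(tab, m$bait_samples, m$control_samples,
                         min_fold = min_fold)
  ranked <- rank_by_abundance(tab, m$bait_samples)
  partition <- resolve_classes(catalog)
  qc <- if (!is.null(m$bait_id))
    bait_qc(ranked, m$bait_id,
            m$histone_ids %||% catalog$histone %||% character())
  else list(status = "no bait declared")
  spec <- class_intensity_fractions(tab, partition, m$bait_samples)
  contam <- contamination_report(tab, partition, m$bait_samples)
  detected <- sum(enr$abundance > 0)
  prec <- if (!is.null(m$reference_ids))
    precision_against_reference(enr$protein_id[enr$enriched],
                                m$reference_ids,
                                m$detected_count %||% detected)
  else list(n_recovered = NA, precision_percent = NA)
  list(row = data.frame(
    method = m$name, failed = FALSE, error = "",
    n_detected = detected, n_enriched = sum(enr$enriched),
    bait_qc = qc$status,
    ptp_fraction = spec$ptp_fraction, pfp_fraction = spec$pfp_fraction,
    specificity_ratio = spec$specificity_ratio,
    contamination_intensity_fraction = contam$intensity_fraction,
    contamination_peptide_fraction = contam$peptide_fraction,
    n_recovered = prec$n_recovered,
    precision_percent = prec$precision_percent,
    stringsAsFactors = FALSE),
    detail = list(enrichment = enr, ranking = ranked, qc = qc,
                  specificity = spec, contamination = contam))
}

#' Run the full synthetic end-to-end pipeline
#'
#' One call chains every stage on generated data with planted ground
#' truth: quant simulation and the two-method benchmark, SILAC differential
#' binding, peak overlap / superenhancer colocalization / top-N
#' concordance / differential occupancy, and the knockdown
#' genetic-interaction analysis integrated with binding sites. Every stage
#' output is checked against its planted truth or invariant; the results
#' of those checks are returned (and must all pass for a healthy run).
#'
#' @param seed Integer seed driving all generators.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSVs plus one `pipeline_summary.json`.
#' @param params Optional list overriding scale parameters:
#'   `n_proteins`, `n_replicates`, `n_silac`, `n_silac_diff`, `n_peaks`,
#'   `coloc_fraction`, `n_superenhancers`, `n_discordant`, `n_regions`,
#'   `n_genes`, `n_targets`.
#' @return List of class `pipeline_bundle` with elements `benchmark`,
#'   `silac`, `occupancy`, `interaction`, `checks` (named logicals),
#'   `all_checks_pass`.
#' @export
run_full_pipeline <- function(seed = 1, outdir = NULL, params = list()) {
  p <- utils::modifyList(list(
    n_proteins = 500, n_replicates = 2, n_silac = 500, n_silac_diff = 50,
    n_peaks = 500, coloc_fraction = 0.6, n_superenhancers = 142,
    n_discordant = 5, n_regions = 1000, n_genes = 2000, n_targets = 200),
    params)
  checks <- c()

  # --- benchmark: clean vs contaminated protocol ---------------------------
  clean <- simulate_quant_experiment(
    n_proteins = p$n_proteins, n_replicates = p$n_replicates, seed = seed)
  sloppy_profile <- method_profile(
    class_factors = c(known_interactor = 2, histone = 3,
                      chromatin_dna_binder = 2, ribosomal = 2,
                      ribonucleoprotein = 2, cytoplasmic_other = 1,
                      affinity_reagent = 20),
    bait_boost = 8)
  sloppy <- simulate_quant_experiment(
    n_proteins = p$n_proteins, n_replicates = p$n_replicates,
    profile = sloppy_profile, seed = seed)
  mk_method <- function(name, sim) list(
    name = name, table = sim$table, catalog = sim$catalog,
    bait_samples = grep("^bait", sim$table$samples$label, value = TRUE),
    control_samples = grep("^ctrl", sim$table$samples$label, value = TRUE),
    bait_id = sim$catalog$bait, histone_ids = sim$catalog$histone,
    reference_ids = sim$catalog$known_interactor)
  bench <- run_benchmark(list(methods = list(
    mk_method("clean", clean), mk_method("contaminated", sloppy))))
  checks["benchmark_ordering"] <-
    identical(bench$ordering, c("clean", "contaminated"))
  checks["benchmark_fractions_sum_to_1"] <- all(vapply(
    bench$details, function(d)
      abs(sum(d$specificity$fractions$fraction) - 1) < 1e-9, logical(1)))
  checks["bait_qc_pass"] <- bench$details$clean$qc$pass

  # --- SILAC differential binding -----------------------------------------
  sil <- simulate_silac_ratios(n_proteins = p$n_silac,
                               n_differential = p$n_silac_diff,
                               seed = seed + 1L)
  de <- test_differential(sil$ratios, alpha = 0.1)
  sens <- mean(de$significant[sil$truth$differential])
  checks["silac_sensitivity"] <- sens >= 0.9
  checks["silac_adj_p_monotone"] <-
    all(de$adj_p >= de$p, na.rm = TRUE)

  # --- genomic occupancy ---------------------------------------------------
  pk <- simulate_peaks(n_peaks_A = p$n_peaks, n_peaks_B = p$n_peaks,
                       colocalization_fraction = p$coloc_fraction,
                       n_superenhancers = p$n_superenhancers,
                       seed = seed + 2L)
  ov <- overlap_peaks(pk$peaks_a, pk$peaks_b)
  checks["peak_overlap_exact"] <-
    ov$n_A_overlapping_B == pk$truth$n_ab_overlap
  coloc <- superenhancer_colocalization(pk$peaks_a, pk$peaks_b,
                                        pk$superenhancers)
  checks["se_coloc_exact"] <- coloc$n_SE_cobound == pk$truth$n_se_covered
  conc_peaks <- simulate_concordant_enrichments(
    pk$peaks_a, n_discordant = p$n_discordant, seed = seed + 3L)
  conc <- top_n_concordance(conc_peaks, N = nrow(conc_peaks))
  checks["concordance_exact"] <- conc$n_discordant == p$n_discordant
  occ <- simulate_occupancy_counts(n_regions = p$n_regions, seed = seed + 4L)
  do <- differential_occupancy(occ$counts, occ$conditions)
  pref_a <- do$region[do$preferential == "A"]
  checks["occupancy_recovery"] <-
    length(intersect(pref_a, occ$truth$preferential)) >=
      0.9 * length(occ$truth$preferential) &&
    length(setdiff(pref_a, occ$truth$preferential)) <=
      0.01 * p$n_regions

  # --- knockdown genetic interactions -------------------------------------
  kd <- simulate_knockdown_counts(n_genes = p$n_genes,
                                  n_targets = p$n_targets, seed = seed + 5L)
  de_single <- de_test(kd$counts, "kd_T")
  de_double <- de_test(kd$counts, "kd_TP")
  gi <- gi_classify(de_single, de_double)
  truth_cls <- kd$truth$gi_label[match(gi$gene_id, kd$truth$gene_id)]
  gi_acc <- if (nrow(gi)) mean(gi$class == truth_cls) else NA
  checks["gi_accuracy"] <- !is.na(gi_acc) && gi_acc >= 0.95
  ga <- simulate_gene_annotation(pk$peaks_a, pk$truth$layout,
                                 n_genes = p$n_genes, fraction_near = 0.1,
                                 seed = seed + 6L)
  near <- assign_nearby_genes(pk$peaks_a, ga$genes)
  checks["proximity_exact"] <-
    setequal(names(near$gene_to_peaks), ga$truth$near)
  gi_bind <- integrate_with_binding(gi, near$gene_to_peaks)
  checks["gi_contingency_total"] <- sum(gi_bind$counts) == nrow(gi)

  bundle <- structure(list(
    benchmark = bench,
    silac = list(result = de, sensitivity = sens, truth = sil$truth),
    occupancy = list(overlap = ov, colocalization = coloc,
                     concordance = conc, differential = do,
                     truth = pk$truth),
    interaction = list(de_single = de_single, de_double = de_double,
                       gi = gi_bind$table, counts = gi_bind$counts,
                       accuracy = gi_acc, truth = kd$truth),
    checks = checks, all_checks_pass = all(checks)),
    class = "pipeline_bundle")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(bench$report, file.path(outdir, "benchmark_report.tsv"))
    write_tsv(de, file.path(outdir, "silac_differential.tsv"))
    write_bed(pk$peaks_a, file.path(outdir, "peaks_a.bed"))
    write_bed(pk$peaks_b, file.path(outdir, "peaks_b.bed"))
    write_tsv(do, file.path(outdir, "differential_occupancy.tsv"))
    write_tsv(gi_bind$table, file.path(outdir, "genetic_interactions.tsv"))
    jsonlite::write_json(list(
      seed = seed,
      checks = as.list(checks),
      silac_sensitivity = sens,
      gi_accuracy = gi_acc,
      specificity_ratios = stats::setNames(
        as.list(bench$report$specificity_ratio), bench$report$method)),
      file.path(outdir, "pipeline_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report (methods ordered by specificity ratio):\n")
  print(x$report[c("method", "n_detected", "n_enriched", "bait_qc",
                   "ptp_fraction", "pfp_fraction", "specificity_ratio")],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle\n")
  for (nm in names(x$checks))
    cat(sprintf("  [%s] %s\n", if (x$checks[[nm]]) "ok" else "FAIL", nm))
  invisible(x)
}
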