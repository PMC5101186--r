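test_that("generators are deterministic under a fixed seed", {
  a <- simulate_quant_experiment(n_proteins = 100, seed = 7)
  b <- simulate_quant_experiment(n_proteins = 100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$table$intensity,
    simulate_quant_experiment(n_proteins = 100, seed = 8)$table$intensity))

  expect_identical(simulate_silac_ratios(seed = 3),
                   simulate_silac_ratios(seed = 3))
  expect_identical(simulate_peaks(n_peaks_A = 50, n_peaks_B = 50,
                                  n_superenhancers = 10, seed = 5),
                   simulate_peaks(n_peaks_A = 50, n_peaks_B = 50,
                                  n_superenhancers = 10, seed = 5))
  expect_identical(simulate_knockdown_counts(n_genes = 100, n_targets = 10,
                                             seed = 2),
                   simulate_knockdown_counts(n_genes = 100, n_targets = 10,
                                             seed = 2))
})

test_that("generator configuration errors are caught", {
  expect_error(simulate_quant_experiment(
    class_proportions = c(histone = 0.5, ribosomal = 0.4)),
    "sum to 1")
  expect_error(simulate_silac_ratios(sigma_rep = -1), "sigma_rep")
  expect_error(simulate_silac_ratios(n_proteins = 10, n_differential = 11),
               "n_differential")
  expect_warning(simulate_knockdown_counts(n_genes = 50, n_targets = 5,
                                           effect_log2 = 0.3, seed = 1),
                 "fold filter")
  expect_error(simulate_peaks(genome_spec = c(chr1 = 1e5), n_peaks_A = 1000,
                              seed = 1),
               "generation error")
})

test_that("noise-free quant simulation puts the planted class order in the ranks", {
  profile <- method_profile(sigma_rep = 0, censor_limit = 0)
  sim <- simulate_quant_experiment(n_proteins = 200, profile = profile,
                                   n_replicates = 2, seed = 13)
  ranked <- rank_by_abundance(sim$table, c("bait_r1", "bait_r2"))
  cls <- sim$truth$class[match(ranked$protein_id, sim$truth$protein_id)]
  n_hist <- sum(sim$truth$class == "histone")
  # bait boost (30) > histone factor (12): bait first, then all histones
  expect_equal(cls[1L], "bait")
  expect_equal(cls[2:(n_hist + 1L)], rep("histone", n_hist))
})

test_that("planted enrichment factor is recovered by the mean fold change", {
  sim <- simulate_quant_experiment(n_proteins = 1000, n_replicates = 2,
                                   seed = 17)
  bait <- sim$table$intensity[, c("bait_r1", "bait_r2")]
  ctrl <- sim$table$intensity[, c("ctrl_r1", "ctrl_r2")]
  spec8 <- sim$truth$class == "known_interactor"  # planted factor 8
  lr <- log10(bait[spec8, ] / ctrl[spec8, ])
  geo_mean_fold <- 10^mean(lr[is.finite(lr)])
  expect_lt(abs(geo_mean_fold - 8) / 8, 0.2)
})

test_that("noise-free SILAC ratios reproduce the planted effects exactly", {
  sil0 <- simulate_silac_ratios(n_proteins = 50, n_differential = 0,
                                sigma_rep = 0, seed = 1)
  expect_true(all(sil0$ratios == 0))
  sil1 <- simulate_silac_ratios(n_proteins = 50, n_differential = 5,
                                effect_log2_range = c(5, 5), sigma_rep = 0,
                                seed = 1)
  diffp <- sil1$truth$differential
  expect_true(all(abs(rowMeans(sil1$ratios[diffp, ])) == 5))
  expect_true(all(rowMeans(sil1$ratios[!diffp, ]) == 0))
})

test_that("planted peak colocalization is exact at the extremes and in between", {
  full <- simulate_peaks(n_peaks_A = 100, n_peaks_B = 100,
                         colocalization_fraction = 1, n_superenhancers = 10,
                         seed = 4)
  expect_equal(overlap_peaks(full$peaks_a, full$peaks_b)$fraction_A_overlapping,
               1)
  none <- simulate_peaks(n_peaks_A = 100, n_peaks_B = 100,
                         colocalization_fraction = 0, n_superenhancers = 10,
                         seed = 4)
  expect_equal(overlap_peaks(none$peaks_a, none$peaks_b)$n_A_overlapping_B, 0)
  mid <- simulate_peaks(n_peaks_A = 500, n_peaks_B = 500,
                        colocalization_fraction = 0.6,
                        n_superenhancers = 50, seed = 4)
  expect_equal(mid$truth$n_ab_overlap, 300)
  expect_equal(overlap_peaks(mid$peaks_a, mid$peaks_b)$n_A_overlapping_B, 300)
})

test_that("planted truth covers every generated entity exactly once", {
  sim <- simulate_quant_experiment(n_proteins = 120, seed = 9)
  expect_setequal(sim$truth$protein_id, sim$table$proteins$protein_id)
  expect_false(anyDuplicated(sim$truth$protein_id) > 0)
  expect_setequal(unlist(sim$catalog), sim$truth$protein_id)

  kd <- simulate_knockdown_counts(n_genes = 150, n_targets = 30, seed = 9)
  expect_setequal(kd$truth$gene_id, rownames(kd$counts$counts))
  expect_equal(sum(kd$truth$is_target), 30)
  expect_true(all(kd$truth$gi_label[kd$truth$is_target] %in%
                    c("independent", "antagonistic", "synergistic")))
  expect_true(all(kd$truth$gi_label[!kd$truth$is_target] == "none"))
})

test_that("knockdown generator plants the stated ratio structure", {
  kd <- simulate_knockdown_counts(n_genes = 300, n_targets = 60, seed = 5)
  tr <- kd$truth[kd$truth$is_target, ]
  expect_true(all(tr$ratio_r[tr$gi_label == "independent"] == 1))
  expect_true(all(tr$ratio_r[tr$gi_label == "antagonistic"] >= 0 &
                    tr$ratio_r[tr$gi_label == "antagonistic"] <= 0.4))
  expect_true(all(tr$ratio_r[tr$gi_label == "synergistic"] >= 1.6 &
                    tr$ratio_r[tr$gi_label == "synergistic"] <= 2.5))
  # condition means follow the planted deltas (Poisson-limit sanity check)
  kd0 <- simulate_knockdown_counts(n_genes = 50, n_targets = 10,
                                   dispersion = 0, n_replicates = 3,
                                   baseline_log2_expr_range = c(10, 12),
                                   seed = 6)
  cm <- kd0$counts
  mt <- rowMeans(cm$counts[, cm$design$condition == "kd_T"])
  mc <- rowMeans(cm$counts[, cm$design$condition == "control"])
  lfc <- log2(mt / mc)
  tgt <- kd0$truth$is_target
  expect_true(all(abs(lfc[tgt] - kd0$truth$delta_single[tgt]) < 0.3))
  expect_true(all(abs(lfc[!tgt]) < 0.3))
})
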