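two_sample_table <- function(intensities, ids = names(intensities)) {
  m <- matrix(intensities, ncol = 1, dimnames = list(ids, "s1"))
  quant_table(m, samples = data.frame(label = "s1", channel = "none",
                                      replicate = 1, condition = "bait"))
}

test_that("class resolution yields a precedence-respecting partition", {
  cat1 <- annotation_catalog(list(chromatin_dna_binder = c("X", "Y"),
                                  known_interactor = "X",
                                  ribosomal = c("Y", "Z")))
  part <- resolve_classes(cat1)
  expect_equal(part[["X"]], "known_interactor")
  expect_equal(part[["Y"]], "chromatin_dna_binder")
  expect_equal(part[["Z"]], "ribosomal")

  # random catalogs: assignment is a partition and matches brute-force
  # "first class in precedence order containing the protein"
  prec <- c("bait", "known_interactor", "histone", "chromatin_dna_binder",
            "ribosomal", "ribonucleoprotein", "affinity_reagent",
            "cytoplasmic_other")
  set.seed(61)
  for (i in 1:20) {
    ids <- sprintf("P%02d", 1:30)
    classes <- lapply(setNames(nm = sample(prec, 5)), function(...)
      sample(ids, sample(0:12, 1)))
    part2 <- resolve_classes(annotation_catalog(classes))
    expect_false(anyDuplicated(names(part2)) > 0)
    expect_setequal(names(part2), unique(unlist(classes)))
    for (p in names(part2)) {
      first <- prec[prec %in% names(classes)][
        vapply(prec[prec %in% names(classes)],
               function(cl) p %in% classes[[cl]], logical(1))][1L]
      expect_equal(unname(part2[p]), first)
    }
  }
})

test_that("class intensity fractions normalize by the total", {
  tab <- two_sample_table(c(PTP1 = 85, PFP1 = 15))
  part <- c(PTP1 = "known_interactor", PFP1 = "ribosomal")
  rep1 <- class_intensity_fractions(tab, part, "s1")
  expect_equal(rep1$ptp_fraction, 0.85)
  expect_equal(rep1$pfp_fraction, 0.15)

  all_one <- class_intensity_fractions(
    two_sample_table(c(A = 3, B = 7)), c(A = "histone", B = "histone"), "s1")
  expect_equal(all_one$fractions$fraction, 1)

  set.seed(62)
  tab3 <- random_quant_table(n_prot = 300, n_samp = 2, zero_frac = 0)
  part3 <- setNames(sample(c("histone", "ribosomal", "cytoplasmic_other"),
                           250, replace = TRUE),
                    tab3$proteins$protein_id[1:250])
  rep3 <- class_intensity_fractions(tab3, part3, tab3$samples$label)
  ab <- rowSums(tab3$intensity)
  for (cl in rep3$fractions$class) {
    ids <- if (cl == "unclassified") setdiff(names(ab), names(part3))
      else names(part3)[part3 == cl]
    expect_equal(rep3$fractions$fraction[rep3$fractions$class == cl],
                 sum(ab[ids]) / sum(ab))
  }
  expect_equal(sum(rep3$fractions$fraction), 1, tolerance = 1e-12)
})

test_that("specificity ratio divides PTP by PFP fractions with guarded edges", {
  mk <- function(ptp, pfp, rest = 0) {
    fr <- data.frame(class = c("known_interactor", "ribosomal", "unclassified"),
                     fraction = c(ptp, pfp, rest))
    list(fractions = fr)
  }
  expect_equal(specificity_ratio(mk(0.85, 0.0625)), 13.6)
  expect_equal(specificity_ratio(mk(0.4, 0.4)), 1)
  expect_equal(specificity_ratio(mk(0.4, 0)), Inf)
  expect_error(specificity_ratio(mk(0, 0, 1)), "undefined ratio")
})

test_that("specificity metrics are invariant under uniform rescaling", {
  sim <- simulate_quant_experiment(n_proteins = 200, seed = 71)
  part <- resolve_classes(sim$catalog)
  labs <- c("bait_r1", "bait_r2")
  base <- class_intensity_fractions(sim$table, part, labs)
  for (c_scale in c(0.001, 3, 1e6)) {
    scaled <- sim$table
    scaled$intensity <- scaled$intensity * c_scale
    rep2 <- class_intensity_fractions(scaled, part, labs)
    expect_equal(rep2$fractions$fraction, base$fractions$fraction)
    expect_equal(rep2$specificity_ratio, base$specificity_ratio)
    expect_equal(contamination_report(scaled, part, labs)$intensity_fraction,
                 contamination_report(sim$table, part, labs)$intensity_fraction)
  }
})

test_that("specificity ratio increases strictly with the planted enrichment", {
  ratios <- sapply(c(2, 4, 8, 16), function(f) {
    pr <- method_profile(class_factors = c(
      known_interactor = f, histone = f, chromatin_dna_binder = f,
      ribosomal = 1, ribonucleoprotein = 1, cytoplasmic_other = 1,
      affinity_reagent = 2))
    sim <- simulate_quant_experiment(profile = pr, seed = 81)
    part <- resolve_classes(sim$catalog)
    class_intensity_fractions(sim$table, part,
                              c("bait_r1", "bait_r2"))$specificity_ratio
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("cumulative class curves are prefix counts with correct endpoints", {
  ranked <- data.frame(protein_id = c("A", "B", "C", "D"), rank = 1:4)
  part <- c(A = "known_interactor", B = "ribosomal", C = "known_interactor",
            D = "cytoplasmic_other")
  cv <- cumulative_class_curve(ranked, part, "known_interactor")
  expect_equal(cv$y_count, c(1, 1, 2, 2))
  expect_equal(cv$y_fraction[4], 1)

  empty <- cumulative_class_curve(ranked, part, "histone")
  expect_equal(empty$y_count, rep(0, 4))
  expect_true(all(is.na(empty$y_fraction)))
  expect_equal(attr(empty, "class_size"), 0)

  expect_error(cumulative_class_curve(ranked, part, "nonsense"),
               "unknown class")

  set.seed(63)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    ids <- sprintf("Q%02d", seq_len(n))
    part2 <- setNames(sample(c("histone", "ribosomal"), n, TRUE), ids)
    rk <- data.frame(protein_id = sample(ids), rank = seq_len(n))
    cv2 <- cumulative_class_curve(rk, part2, "histone")
    oracle <- cumsum(part2[rk$protein_id] == "histone")
    expect_equal(cv2$y_count, unname(oracle))
    expect_true(all(diff(cv2$y_count) >= 0))
    expect_equal(cv2$y_count[n], sum(part2 == "histone"))
  }
})

test_that("contamination accounting sums the affinity-reagent class", {
  tab <- two_sample_table(c(IGG = 100, A = 500, B = 400))
  part <- c(IGG = "affinity_reagent", A = "histone", B = "ribosomal")
  rep1 <- contamination_report(tab, part, "s1")
  expect_equal(rep1$intensity_fraction, 0.1)
  none <- contamination_report(tab, c(A = "histone"), "s1")
  expect_equal(none$intensity, 0)
  expect_equal(none$peptide_fraction, 0)

  # washed vs bead-digest profile: planted 100x reagent factor difference
  washed <- method_profile()
  dirty_factors <- washed$class_factors
  dirty_factors["affinity_reagent"] <- dirty_factors["affinity_reagent"] * 100
  dirty <- method_profile(class_factors = dirty_factors)
  s1 <- simulate_quant_experiment(n_proteins = 800, profile = washed,
                                  seed = 91)
  s2 <- simulate_quant_experiment(n_proteins = 800, profile = dirty,
                                  seed = 91)
  p1 <- resolve_classes(s1$catalog); p2 <- resolve_classes(s2$catalog)
  i1 <- contamination_report(s1$table, p1, c("bait_r1", "bait_r2"))$intensity
  i2 <- contamination_report(s2$table, p2, c("bait_r1", "bait_r2"))$intensity
  expect_gt(i2 / i1, 50)
  expect_lt(i2 / i1, 200)
})
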