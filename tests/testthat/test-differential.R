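silac_table <- function(heavy, light, ids = NULL) {
  # heavy/light: matrices proteins x replicates
  r <- ncol(heavy)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nrow(heavy)))
  m <- cbind(heavy, light)
  rownames(m) <- ids
  colnames(m) <- c(sprintf("H%d", seq_len(r)), sprintf("L%d", seq_len(r)))
  samples <- data.frame(label = colnames(m),
                        channel = rep(c("heavy", "light"), each = r),
                        replicate = rep(seq_len(r), 2),
                        condition = rep(c("cond2iL", "serum"), each = r))
  quant_table(m, samples = samples)
}

pairing2 <- function(r = 2) data.frame(replicate = seq_len(r),
                                       heavy = sprintf("H%d", seq_len(r)),
                                       light = sprintf("L%d", seq_len(r)))

test_that("SILAC ratios are log2(heavy/light) with missing channels dropped", {
  tab <- silac_table(heavy = matrix(c(8, 8, 0, 4), 2, 2, byrow = TRUE),
                     light = matrix(c(2, 2, 3, 1), 2, 2, byrow = TRUE))
  r <- compute_ratios(tab, pairing2(), median_center = FALSE)
  expect_equal(r[1, ], c(rep1 = 2, rep2 = 2))
  expect_true(is.na(r[2, 1]))      # heavy channel not detected
  expect_equal(r[2, 2], 2, ignore_attr = TRUE)

  set.seed(101)
  h <- matrix(10^runif(60, 3, 7), 20, 3)
  l <- matrix(10^runif(60, 3, 7), 20, 3)
  tab2 <- silac_table(h, l)
  r2 <- compute_ratios(tab2, pairing2(3), median_center = FALSE)
  expect_equal(unname(r2), log2(h / l))  # brute-force division oracle
  # median centering makes each replicate's median 0
  r3 <- compute_ratios(tab2, pairing2(3))
  expect_equal(unname(apply(r3, 2, median)), rep(0, 3))
})

test_that("one-sample test handles degenerate ratio vectors as specified", {
  m <- rbind(zero = c(0, 0, 0), const = c(2, 2, 2), one = c(1, NA, NA))
  res <- test_differential(m, min_replicates = 2)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(res$zero_variance[2])
  expect_equal(res$p[2], .Machine$double.xmin)
  expect_false(res$tested[3])
  expect_true(is.na(res$p[3]))

  single <- test_differential(rbind(p1 = c(0.5, 1.2, 0.9)))
  expect_equal(single$adj_p, single$p)  # BH identity for one test
})

test_that("t statistics and BH adjustment match independent oracles", {
  set.seed(102)
  m <- matrix(rnorm(60, sd = 1.2), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20), NULL))
  res <- test_differential(m)
  for (i in seq_len(20)) {
    tt <- t.test(m[i, ])
    expect_equal(res$t[i], unname(tt$statistic))
    expect_equal(res$p[i], tt$p.value)
  }
  expect_equal(res$adj_p, bh_oracle(res$p))
  expect_equal(res$adj_p, p.adjust(res$p, "BH"))
  expect_true(all(res$adj_p >= res$p))
  # larger random instances against the from-definition BH oracle
  for (i in 1:5) {
    p <- runif(sample(50:1000, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("null SILAC simulations keep the significant fraction below 0.12", {
  frac <- vapply(1:50, function(s) {
    sil <- simulate_silac_ratios(n_proteins = 200, n_differential = 0,
                                 seed = 1000 + s)
    mean(test_differential(sil$ratios, alpha = 0.1)$significant)
  }, numeric(1))
  expect_true(all(frac <= 0.12))
})

test_that("set intersection with control subtraction matches set algebra", {
  expect_equal(subtract_control_and_intersect(
    list(c("A", "B", "C"), c("B", "C"), c("B", "C", "D")), "C"), "B")
  expect_setequal(subtract_control_and_intersect(
    list(c("A", "B"), c("B", "A")), character()), c("A", "B"))
  expect_error(subtract_control_and_intersect(list(c("A"))), "two sets")
  set.seed(103)
  for (i in 1:20) {
    sets <- lapply(1:3, function(...) sample(LETTERS, sample(5:20, 1)))
    ctrl <- sample(LETTERS, 5)
    expect_setequal(subtract_control_and_intersect(sets, ctrl),
                    setdiff(intersect(intersect(sets[[1]], sets[[2]]),
                                      sets[[3]]), ctrl))
  }
})

test_that("ratio-matrix clustering recovers structure and matches the oracle", {
  set.seed(104)
  base <- rnorm(40)
  mat <- cbind(Oct4 = base + rnorm(40, sd = 0.1),
               Sox2 = base + rnorm(40, sd = 0.1),
               Nanog = base + rnorm(40, sd = 0.1),
               Cdh1 = rnorm(40))
  rownames(mat) <- sprintf("P%02d", 1:40)
  cl <- cluster_ratio_matrix(mat)
  # the uncorrelated bait is the last-merged column leaf
  merges <- cl$col_hclust$merge
  last <- merges[nrow(merges), ]
  expect_true(-match("Cdh1", colnames(mat)) %in% last)

  # identical columns merge at distance 0
  mat2 <- cbind(a = base, b = base, c = rnorm(40))
  cl2 <- cluster_ratio_matrix(mat2)
  expect_equal(cl2$col_hclust$height[1], 0)

  # merge heights equal the naive average-linkage oracle
  for (i in 1:20) {
    m <- matrix(rnorm(24), 6, 4,
                dimnames = list(sprintf("r%d", 1:6), sprintf("c%d", 1:4)))
    got <- cluster_ratio_matrix(m, distance = "euclidean")
    expect_equal(sort(got$row_hclust$height),
                 average_linkage_heights(dist(m)))
  }

  # row permutation changes leaf order only, not the leaf sets per subtree
  perm <- sample(nrow(mat))
  clp <- cluster_ratio_matrix(mat[perm, ])
  expect_setequal(clp$row_order, cl$row_order)
  expect_equal(sort(clp$row_hclust$height), sort(cl$row_hclust$height))

  # constant column under correlation distance falls back with a flag
  mat3 <- cbind(a = base, b = rep(1, 40))
  fb <- cluster_ratio_matrix(mat3)
  expect_true("cols" %in% fb$fallback)
})

test_that("PTM shifts are parent-relative deltas with orphan handling", {
  prot <- c(PA = 2, PB = 0.5)
  ptm <- data.frame(site_id = c("s1", "s2", "s3"),
                    protein_id = c("PA", "PB", "PX"),
                    ratio = c(2, 3, 1))
  expect_warning(res <- ptm_shift(ptm, prot), "no parent protein")
  expect_equal(res$delta, c(0, 2.5))
  expect_equal(res$flagged, c(FALSE, TRUE))
  set.seed(105)
  ptm2 <- data.frame(site_id = sprintf("s%d", 1:30),
                     protein_id = sample(names(prot), 30, TRUE),
                     ratio = rnorm(30))
  res2 <- ptm_shift(ptm2, prot)
  expect_equal(res2$delta, ptm2$ratio - unname(prot[ptm2$protein_id]))
})
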