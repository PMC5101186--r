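# Independent brute-force oracles, deliberately written from the textbook
# definitions and kept free of any package internals.

# Benjamini-Hochberg from the definition: sort, p * n / rank, running min
# from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# O(n^2) interval overlap count: how many intervals of a share >= min_bp
# bases with some interval of b (0-based half-open).
brute_overlap_count <- function(a, b, min_bp = 1) {
  sum(vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    any(pmin(a$end[i], b$end[same]) - pmax(a$start[i], b$start[same]) >= min_bp)
  }, logical(1)))
}

# all-pairs TSS-to-peak distance under the last-covered-base convention
brute_nearby <- function(peaks, genes, max_distance) {
  out <- NULL
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(genes))) {
    if (peaks$chrom[i] != genes$chrom[j]) next
    d <- max(0, peaks$start[i] - genes$tss[j],
             genes$tss[j] - (peaks$end[i] - 1))
    if (d < max_distance)
      out <- rbind(out, data.frame(peak = peaks$name[i],
                                   gene_id = genes$gene_id[j],
                                   distance = d, stringsAsFactors = FALSE))
  }
  out
}

# naive agglomerative average-linkage clustering; returns sorted merge
# heights (Lance-Williams update from the definition)
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    heights <- c(heights, bestd)
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# random valid peak set on a small genome (may contain overlapping peaks)
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_width = 500) {
  start <- sample(0:(max_pos - max_width), n, replace = TRUE)
  peak_set(chrom = sample(chroms, n, replace = TRUE),
           start = start,
           end = start + sample(seq_len(max_width), n, replace = TRUE),
           name = sprintf("rp_%03d", seq_len(n)),
           enrichment = round(stats::runif(n, 0, 20), 3))
}

# random quant table fixture
random_quant_table <- function(n_prot = 20, n_samp = 4, zero_frac = 0.1) {
  m <- matrix(round(10^stats::runif(n_prot * n_samp, 3, 8), 4),
              n_prot, n_samp)
  m[stats::runif(length(m)) < zero_frac] <- 0
  rownames(m) <- sprintf("P%03d", seq_len(n_prot))
  pep <- matrix(ifelse(m > 0, sample(1:40, length(m), replace = TRUE), 0L),
                n_prot, n_samp, dimnames = dimnames(m))
  samples <- data.frame(label = sprintf("s%d", seq_len(n_samp)),
                        channel = "none",
                        replicate = seq_len(n_samp),
                        condition = "bait", stringsAsFactors = FALSE)
  colnames(m) <- colnames(pep) <- samples$label
  quant_table(m, pep, samples)
}
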