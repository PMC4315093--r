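# likelihood of unphased two-locus genotype counts under haplotype
# frequencies with marginals fixed at the observed allele frequencies;
# used as a 1-parameter grid-search oracle for the EM
loglik_f11 <- function(f11, pA1, pB1, g_a, g_b) {
  f <- c(aa = f11, ab = pA1 - f11, ba = pB1 - f11, bb = 1 - pA1 - pB1 + f11)
  if (any(f < -1e-12)) return(-Inf)
  f <- pmax(f, 0)
  # P(gA = i, gB = j): convolve two haplotype draws
  hap_a <- c(aa = 0, ab = 0, ba = 1, bb = 1)  # allele_b dose at locus A
  hap_b <- c(aa = 0, ab = 1, ba = 0, bb = 1)
  pg <- matrix(0, 3, 3)
  for (h1 in 1:4) for (h2 in 1:4) {
    pg[hap_a[h1] + hap_a[h2] + 1, hap_b[h1] + hap_b[h2] + 1] <-
      pg[hap_a[h1] + hap_a[h2] + 1, hap_b[h1] + hap_b[h2] + 1] +
      f[h1] * f[h2]
  }
  sum(log(pg[cbind(g_a + 1, g_b + 1)]))
}

test_that("EM equals direct haplotype counting when no double heterozygotes", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 30
    hapA1 <- rbinom(n, 1, 0.4); hapA2 <- rbinom(n, 1, 0.4)
    hapB1 <- ifelse(runif(n) < 0.7, hapA1, rbinom(n, 1, 0.5))
    hapB2 <- ifelse(runif(n) < 0.7, hapA2, rbinom(n, 1, 0.5))
    g_a <- hapA1 + hapA2
    g_b <- hapB1 + hapB2
    dh <- g_a == 1 & g_b == 1
    if (all(dh) || sum(!dh) < 2) next
    f <- haplotype_freqs_em(g_a[!dh], g_b[!dh])
    r2_direct <- r2_from_haplotypes(c(hapA1[!dh], hapA2[!dh]),
                                    c(hapB1[!dh], hapB2[!dh]))
    expect_equal(unname(r2_pair(f[1], f[2], f[3], f[4])), r2_direct,
                 tolerance = 1e-9)
  }
})

test_that("EM finds the grid-search maximum with one double heterozygote", {
  g_a <- c(0L, 0L, 2L, 2L, 1L, 1L, 1L)
  g_b <- c(0L, 0L, 2L, 1L, 0L, 2L, 1L)   # last individual double-het
  f <- haplotype_freqs_em(g_a, g_b)
  pA1 <- 1 - sum(g_a) / (2 * length(g_a))   # freq of allele_a at A
  pB1 <- 1 - sum(g_b) / (2 * length(g_b))
  lo <- max(0, pA1 + pB1 - 1)
  hi <- min(pA1, pB1)
  grid <- seq(lo, hi, by = 1e-6)
  ll <- vapply(grid, loglik_f11, numeric(1), pA1, pB1, g_a, g_b)
  f11_hat <- grid[which.max(ll)]
  expect_equal(unname(f["f11"]), f11_hat, tolerance = 1e-5)
  # EM marginals equal observed allele frequencies
  expect_equal(unname(f["f11"] + f["f12"]), pA1, tolerance = 1e-9)
  expect_equal(unname(f["f11"] + f["f21"]), pB1, tolerance = 1e-9)
})

test_that("all double heterozygotes converge to the symmetric stationary point", {
  f <- haplotype_freqs_em(rep(1L, 10), rep(1L, 10))
  expect_equal(as.numeric(f), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(unname(f["f11"] + f["f12"]), 0.5, tolerance = 1e-12)
})

test_that("r2_pair reproduces hand-computed values and conventions", {
  expect_equal(r2_pair(0.5, 0, 0, 0.5), 1)
  # independence: f11 = fA1 * fB1
  pa <- 0.3; pb <- 0.6
  expect_equal(r2_pair(pa * pb, pa * (1 - pb), (1 - pa) * pb,
                       (1 - pa) * (1 - pb)), 0, tolerance = 1e-12)
  expect_equal(r2_pair(0.4, 0.1, 0.1, 0.4), 0.36, tolerance = 1e-12)
  # monomorphic marginal
  expect_equal(r2_pair(0.5, 0.5, 0, 0), 0)
})

test_that("r2 is symmetric under locus swap and allele relabelling", {
  set.seed(11)
  for (i in 1:30) {
    f <- as.numeric(stats::rmultinom(1, 200, runif(4))) / 200
    r <- r2_pair(f[1], f[2], f[3], f[4])
    expect_equal(r2_pair(f[1], f[3], f[2], f[4]), r, tolerance = 1e-12) # swap loci
    expect_equal(r2_pair(f[3], f[4], f[1], f[2]), r, tolerance = 1e-12) # relabel A
    expect_equal(r2_pair(f[2], f[1], f[4], f[3]), r, tolerance = 1e-12) # relabel B
  }
})

test_that("ld_scan windowing matches the stated pair rules", {
  x <- random_cohort(n = 20, m = 10, seed = 5)
  x$markers$chrom <- rep("1", 10)
  x$markers$pos_bp <- as.integer(c(1e4, 2e4, 3e4, 5e6, 5.01e6, 5.02e6,
                                   2e7, 3.2e7, 3.21e7, 3.3e7))
  x <- geno_cohort(x$calls, x$markers, x$samples)
  # 3 equally spaced markers well inside both windows -> exactly 3 pairs
  sub <- cohort_subset(x, marker_ids = x$markers$marker_id[1:3])
  expect_identical(nrow(ld_scan(sub)), 3L)
  # markers 11 Mb apart -> excluded by the kb window
  sub2 <- cohort_subset(x, marker_ids = x$markers$marker_id[6:7])
  expect_identical(nrow(ld_scan(sub2)), 0L)
  # marker-count window
  sub3 <- cohort_subset(x, marker_ids = x$markers$marker_id[1:3])
  expect_identical(nrow(ld_scan(sub3, window_snps = 1L)), 2L)
})

test_that("ld_scan equals a brute-force all-pairs oracle on a simulated chromosome", {
  sim <- sved_sim(seed = 404, founder_markers = 600, duration = 60)
  x <- sim$cohort
  recs <- ld_scan(x, window_snps = 50L, window_kb = 2000)
  # oracle: enumerate all pairs, filter by both windows, scalar EM each
  mk <- x$markers
  pairs <- t(utils::combn(seq_len(nrow(mk)), 2))
  keep <- (pairs[, 2] - pairs[, 1] <= 50) &
    (mk$pos_bp[pairs[, 2]] - mk$pos_bp[pairs[, 1]] <= 2000 * 1000)
  pairs <- pairs[keep, , drop = FALSE]
  expect_identical(nrow(recs), nrow(pairs))
  r2_oracle <- vapply(seq_len(nrow(pairs)), function(k) {
    f <- haplotype_freqs_em(x$calls[, pairs[k, 1]], x$calls[, pairs[k, 2]])
    unname(r2_pair(f[1], f[2], f[3], f[4]))
  }, numeric(1))
  # both routes are EM to 1e-8 on frequencies; stopping-point differences
  # leave r2 agreeing far tighter than any scientific use of it
  expect_equal(recs$r2, r2_oracle, tolerance = 1e-6)
  expect_identical(recs$marker_a, mk$marker_id[pairs[, 1]])
  # deterministic ordering: by left then right position
  expect_false(is.unsorted(recs$pos_a))
})

test_that("ld_scan output is invariant to input marker order", {
  x <- random_cohort(n = 15, m = 30, seed = 9)
  perm <- sample(30)
  y <- geno_cohort(x$calls[, perm], x$markers[perm, ], x$samples)
  expect_equal(ld_scan(x), ld_scan(y))
})

test_that("decay_curve bins and summarises as specified", {
  recs <- tibble::tibble(population = "p", chrom = "1",
                         distance_bp = c(5000, 5000, 15000, 30000),
                         r2 = c(0.4, 0.4, 0.2, 0.4))
  dc <- decay_curve(recs)
  expect_equal(dc$mean_r2[dc$bin_lower_kb == 0], 0.4)
  expect_equal(dc$sd_r2[dc$bin_lower_kb == 0], 0)
  expect_equal(dc$mean_r2[dc$bin_lower_kb == 10], 0.2)
  expect_equal(dc$mean_r2[dc$bin_lower_kb == 20], 0.4)
  expect_identical(dc$n_pairs[dc$bin_lower_kb == 40], 0L)
  expect_identical(nrow(dc), 10L)
  # bin edges are half-open (lower, upper]
  recs2 <- tibble::tibble(distance_bp = c(10000, 10001), r2 = c(1, 0))
  dc2 <- decay_curve(recs2)
  expect_equal(dc2$mean_r2[dc2$bin_lower_kb == 0], 1)
  expect_equal(dc2$mean_r2[dc2$bin_lower_kb == 10], 0)
  # grouping oracle on a simulated record set
  set.seed(21)
  recs3 <- tibble::tibble(distance_bp = sample.int(5e6, 500),
                          r2 = runif(500))
  dc3 <- decay_curve(recs3)
  edges <- c(0, 10, 20, 40, 60, 100, 200, 500, 1000, 2000, 5000) * 1000
  for (b in seq_len(10)) {
    in_bin <- recs3$distance_bp > edges[b] & recs3$distance_bp <= edges[b + 1]
    if (any(in_bin)) {
      expect_equal(dc3$mean_r2[b], mean(recs3$r2[in_bin]))
      expect_equal(dc3$sd_r2[b], sd(recs3$r2[in_bin]))
    }
  }
})
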