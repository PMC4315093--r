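test_that("presets carry the two regimes' thresholds", {
  s <- qc_preset("structure")
  expect_equal(s$maf_min, 0.02)
  expect_true(is.na(s$hwe_p_min))
  expect_equal(s$kinship_max, 0.45)
  expect_equal(s$ld_prune_r2, 0.2)
  l <- qc_preset("ld")
  expect_equal(l$maf_min, 0.05)
  expect_equal(l$hwe_p_min, 0.001)
  expect_equal(l$marker_missing_max, 0.05)
  expect_true(is.na(l$ld_prune_r2))
  expect_error(qc_config(maf_min = 1.5), "config error")
})

test_that("marker filters catch the planted single-marker cases", {
  # all-zero marker is monomorphic
  x <- random_cohort(n = 20, m = 5, seed = 2)
  x$calls[, 3] <- 0L
  x <- geno_cohort(x$calls, x$markers, x$samples)
  fm <- filter_markers(x, qc_preset("ld"))
  expect_true(x$markers$marker_id[3] %in% fm$removed$monomorphic)

  # 100 samples, 4 copies of the minor allele: MAF 0.02 <= 0.05 -> removed
  set.seed(4)
  calls <- matrix(rbinom(100 * 3, 2L, 0.4), 100, 3)
  calls[, 2] <- 0L
  calls[sample(100, 4), 2] <- 1L
  x <- geno_cohort(calls, data.frame(marker_id = c("a", "b", "c"),
                                     chrom = "1", pos_bp = c(1L, 2L, 3L)),
                   data.frame(sample_id = sprintf("s%03d", 1:100),
                              population = "p"))
  fm <- filter_markers(x, qc_preset("ld"))
  expect_identical(fm$removed$maf, "b")

  # sex and unmapped markers go first
  x <- random_cohort(n = 10, m = 6, seed = 3)
  x$markers$chrom <- c("1", "Z", "W", "0", "LGE22", "2")
  x$markers$pos_bp <- c(10L, 20L, 30L, 40L, 50L, 60L)
  x <- geno_cohort(x$calls, x$markers, x$samples)
  fm <- filter_markers(x, qc_preset("ld"))
  expect_setequal(fm$removed$sex_chromosome,
                  x$markers$marker_id[x$markers$chrom %in% c("Z", "W")])
  expect_setequal(fm$removed$unmapped,
                  x$markers$marker_id[x$markers$chrom %in% c("0", "LGE22")])
})

test_that("attrition counts equal the planted-violation ledger", {
  sim <- sved_sim(seed = 77, ne = 60, n_sample = 20, founder_markers = 700,
                  duration = 40, maf_floor = 0.1)
  sim <- plant_violations(sim, list(n_monomorphic = 4, n_low_maf = 3,
                                    n_hwe = 3, n_high_missing_marker = 2,
                                    n_high_missing_sample = 1))
  qc <- qc_cohort(sim$cohort, "ld")
  led <- split(sim$ledger$planted$id, sim$ledger$planted$kind)
  expect_setequal(qc$removed$monomorphic, led$monomorphic)
  expect_setequal(qc$removed$maf, led$maf)
  expect_setequal(qc$removed$hwe, led$hwe)
  expect_setequal(qc$removed$marker_missing, led$marker_missing)
  expect_setequal(qc$removed$sample_missing, led$sample_missing)
  # report conservation: removed + retained = input, per domain
  rep <- qc$report
  m_in <- n_markers(sim$cohort)
  m_rep <- rep[rep$domain == "marker", ]
  expect_identical(sum(m_rep$removed) + m_rep$retained[nrow(m_rep)], m_in)
  s_rep <- rep[rep$domain == "sample", ]
  expect_identical(sum(s_rep$removed) + s_rep$retained[nrow(s_rep)],
                   n_samples(sim$cohort))
})

test_that("the QC pipeline is idempotent", {
  sim <- sved_sim(seed = 31, ne = 50, n_sample = 20, founder_markers = 400,
                  duration = 40)
  sim <- plant_violations(sim, list(n_monomorphic = 2, n_hwe = 2))
  qc1 <- qc_cohort(sim$cohort, "ld")
  qc2 <- qc_cohort(qc1$cohort, "ld")
  expect_identical(qc2$cohort$calls, qc1$cohort$calls)
  expect_identical(qc2$cohort$markers, qc1$cohort$markers)
  expect_true(all(qc2$report$removed == 0))
})

test_that("drop_related greedy removal leaves no pair at threshold", {
  x <- random_cohort(n = 10, m = 500, seed = 8)
  kin <- kinship_ibd(x, min_overlap = 10)
  # no pair above threshold -> identity
  out <- drop_related(x, kin, threshold = 1)
  expect_identical(n_samples(out), 10L)
  # one planted duo at 0.6 -> exactly one member removed
  kin2 <- kin
  kin2$pi_hat[1] <- 0.6
  out <- drop_related(x, kin2, threshold = 0.45)
  expect_identical(n_samples(out), 9L)
  expect_true(attr(out, "removed") %in% c(kin2$sample_1[1], kin2$sample_2[1]))
  # planted clique of 3: retained set has no pair >= threshold and matches
  # the best achievable retained size found by brute force over subsets
  kin3 <- kin
  clique <- c("s001", "s002", "s003")
  kin3$pi_hat[kin3$sample_1 %in% clique & kin3$sample_2 %in% clique] <- 0.7
  out <- drop_related(x, kin3, threshold = 0.45)
  keep <- out$samples$sample_id
  viol <- kin3$pi_hat >= 0.45 & kin3$sample_1 %in% keep & kin3$sample_2 %in% keep
  expect_false(any(viol))
  best <- 0
  ids <- x$samples$sample_id
  for (k in length(ids):1) {
    combs <- utils::combn(ids, k, simplify = FALSE)
    ok <- vapply(combs, function(s)
      !any(kin3$pi_hat >= 0.45 & kin3$sample_1 %in% s & kin3$sample_2 %in% s),
      logical(1))
    if (any(ok)) { best <- k; break }
  }
  expect_identical(length(keep), best)
})

test_that("LD pruning removes correlated markers and only those needed", {
  # two perfectly correlated markers -> one survives
  set.seed(12)
  g <- rbinom(40, 2, 0.5)
  calls <- cbind(g, g, rbinom(40, 2, 0.5))
  x <- geno_cohort(calls, data.frame(marker_id = c("a", "b", "c"),
                                     chrom = "1", pos_bp = c(1L, 2L, 3L)),
                   data.frame(sample_id = sprintf("s%02d", 1:40),
                              population = "p"))
  keep <- prune_ld(x, r2_threshold = 0.2)
  expect_identical(sort(c(keep)), sort(c("c", setdiff(c("a", "b"), attr(keep, "removed")))))
  expect_identical(length(attr(keep, "removed")), 1L)

  # independent markers -> identity
  x2 <- random_cohort(n = 50, m = 12, seed = 13)
  keep2 <- prune_ld(x2, r2_threshold = 0.9)
  expect_identical(length(keep2), 12L)

  # planted correlation block: survivors verified pair-by-pair
  sim <- sved_sim(seed = 55, ne = 40, n_sample = 25, founder_markers = 200,
                  duration = 30)
  x3 <- sim$cohort
  keep3 <- prune_ld(x3, r2_threshold = 0.2, window_markers = 20, step = 2)
  sub <- cohort_subset(x3, marker_ids = keep3)
  if (n_markers(sub) >= 2) {
    idx <- match(sub$markers$marker_id, x3$markers$marker_id)
    pr <- t(utils::combn(seq_len(n_markers(sub)), 2))
    within <- abs(idx[pr[, 2]] - idx[pr[, 1]]) < 20
    for (k in which(within)) {
      f <- haplotype_freqs_em(sub$calls[, pr[k, 1]], sub$calls[, pr[k, 2]])
      expect_lt(r2_pair(f[1], f[2], f[3], f[4]), 0.2)
    }
  }
  expect_error(prune_ld(x3, window_markers = 1), "config error")
})
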