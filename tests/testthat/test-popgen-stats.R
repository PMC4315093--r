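test_that("marker statistics match forced-frequency hand cases", {
  # all heterozygotes, 10 samples
  x <- geno_cohort(matrix(1L, 10, 1),
                   data.frame(marker_id = "m", chrom = "1", pos_bp = 1L),
                   data.frame(sample_id = sprintf("s%02d", 1:10),
                              population = "p"))
  ms <- marker_stats(x)
  expect_equal(ms$h_o, 1)
  expect_equal(ms$freq_b, 0.5)
  expect_equal(ms$h_e, 2 * 0.25 * 20 / 19)
  # monomorphic marker
  x2 <- geno_cohort(matrix(0L, 10, 1),
                    data.frame(marker_id = "m", chrom = "1", pos_bp = 1L),
                    x$samples)
  ms2 <- marker_stats(x2)
  expect_equal(ms2$maf, 0)
  expect_equal(ms2$h_o, 0)
  expect_equal(ms2$h_e, 0)
})

test_that("marker statistics equal a direct counting oracle exactly", {
  x <- random_cohort(n = 25, m = 80, miss = 0.1, n_pop = 2, seed = 14)
  ms <- marker_stats(x)
  for (k in sample(nrow(ms), 25)) {
    pop <- ms$population[k]
    g <- x$calls[x$samples$population == pop, ms$marker_id[k]]
    g <- g[!is.na(g)]
    expect_identical(ms$n_called[k], length(g))
    expect_equal(ms$h_o[k], sum(g == 1) / length(g))
    p <- sum(g) / (2 * length(g))
    expect_equal(ms$freq_b[k], p)
    expect_equal(ms$maf[k], min(p, 1 - p))
    expect_equal(ms$h_e[k],
                 2 * p * (1 - p) * (2 * length(g)) / (2 * length(g) - 1))
  }
  expect_true(all(ms$maf <= 0.5 & ms$maf >= 0))
  expect_true(all(ms$h_o >= 0 & ms$h_o <= 1 & ms$h_e >= 0 & ms$h_e <= 1))
})

test_that("inbreeding F hits its fixed points", {
  # individual matching HW expectation exactly: F = 0
  set.seed(15)
  m <- 400
  # construct a population where one individual's observed homozygosity
  # equals its expectation by brute-force check of the formula
  x <- random_cohort(n = 30, m = m, seed = 15)
  fi <- inbreeding_f(x)
  ms <- allele_freq(x)
  # direct recomputation oracle
  for (k in c(1, 17)) {
    g <- x$calls[k, ]
    p <- ms$freq_b
    n <- ms$n_called * 2
    ehom <- sum(1 - 2 * p * (1 - p) * n / (n - 1))
    ohom <- sum(g != 1L)
    expect_equal(fi$f[k], (ohom - ehom) / (m - ehom))
  }
  # fully homozygous individual at all markers -> F = 1
  calls <- x$calls
  calls[5, ] <- ifelse(calls[5, ] == 1L, 0L, calls[5, ])
  y <- geno_cohort(calls, x$markers, x$samples)
  fy <- inbreeding_f(y)
  expect_equal(fy$f[5], 1)
  expect_true(all(fy$reliable))
})

test_that("mean F under partial selfing approaches Wright's equilibrium", {
  # selfing rate s -> equilibrium F = s/(2-s); forward-simulate unlinked loci
  s <- 0.4; n <- 100; m <- 5000; gens <- 15
  set.seed(16)
  p <- runif(m, 0.2, 0.8)
  H1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
  H2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
  for (g in seq_len(gens)) {
    p1 <- sample.int(n, n, replace = TRUE)
    p2 <- ifelse(runif(n) < s, p1, sample.int(n, n, replace = TRUE))
    pick <- function(P) {
      sel <- matrix(runif(n * m) < 0.5, n, m)
      ifelse(sel, H1[P, ], H2[P, ])
    }
    A1 <- pick(p1); A2 <- pick(p2)
    H1 <- A1; H2 <- A2
  }
  x <- geno_cohort(H1 + H2,
                   data.frame(marker_id = sprintf("m%05d", 1:m), chrom = "1",
                              pos_bp = 1:m * 10L),
                   data.frame(sample_id = sprintf("i%03d", 1:n),
                              population = "p"))
  fi <- inbreeding_f(x)
  expect_lt(abs(mean(fi$f) - s / (2 - s)), 0.05)
})

test_that("MAF spectrum uses the stated bins and sums to one", {
  expect_warning(sp0 <- maf_spectrum(numeric(0)), "no polymorphic")
  expect_true(all(sp0$proportion == 0))
  sp <- maf_spectrum(rep(0.25, 10))
  expect_equal(sp$proportion[sp$bin_lower == 0.2], 1)
  expect_equal(sum(sp$proportion), 1)
  # histogram oracle on a uniform fixture
  set.seed(17)
  maf <- runif(500, 0, 0.5)
  sp2 <- maf_spectrum(maf)
  edges <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  h <- hist(maf, breaks = edges, plot = FALSE, right = TRUE,
            include.lowest = TRUE)
  expect_equal(sp2$n_markers, h$counts)
  expect_equal(sum(sp2$proportion), 1)
})

test_that("PCA separates simulated populations and respects identities", {
  x <- bn_cohort(n_per_pop = 30, m = 400, fst = 0.1, seed = 18)
  pc <- pca_genotypes(x, k = 4)
  # silhouette of PC1 against the true labels
  lab <- pc$population
  sil <- vapply(seq_len(nrow(pc)), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    a <- mean(abs(pc$PC1[i] - pc$PC1[own]))
    b <- mean(abs(pc$PC1[i] - pc$PC1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # duplicated sample -> identical coordinates
  calls <- rbind(x$calls, x$calls[1, ])
  y <- geno_cohort(calls, x$markers,
                   rbind(x$samples,
                         data.frame(sample_id = "dup", population = "popA")))
  pcy <- pca_genotypes(y, k = 3)
  expect_equal(unlist(pcy[pcy$sample_id == "dup", c("PC1", "PC2", "PC3")]),
               unlist(pcy[pcy$sample_id == "s001", c("PC1", "PC2", "PC3")]),
               tolerance = 1e-9)

  # sample-order permutation invariance (up to the fixed sign convention)
  perm <- sample(n_samples(x))
  z <- geno_cohort(x$calls[perm, ], x$markers, x$samples[perm, ])
  pcz <- pca_genotypes(z, k = 3)
  m1 <- as.matrix(pc[match(pcz$sample_id, pc$sample_id), c("PC1", "PC2", "PC3")])
  m2 <- as.matrix(pcz[, c("PC1", "PC2", "PC3")])
  expect_equal(abs(m1), abs(m2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("null PCA shows no eigenvalue outlier beyond the bulk edge", {
  set.seed(19)
  n <- 50; m <- 1000
  p <- runif(m, 0.2, 0.8)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  x <- geno_cohort(calls,
                   data.frame(marker_id = sprintf("m%04d", 1:m), chrom = "1",
                              pos_bp = 1:m * 50L),
                   data.frame(sample_id = sprintf("s%03d", 1:n),
                              population = "p"))
  pc <- pca_genotypes(x, k = 5)
  eig <- attr(pc, "eigenvalues")
  edge <- (1 + sqrt(n / m))^2
  expect_lt(eig[1], 1.5 * edge)
})

test_that("diversity summary aggregates marker stats and F with a t-test", {
  x <- random_cohort(n = 30, m = 200, n_pop = 2, seed = 20)
  ds <- diversity_summary(x)
  expect_identical(nrow(ds), 2L)
  expect_true(all(ds$mean_ho >= 0 & ds$mean_ho <= 1))
  expect_true(all(ds$mean_maf <= 0.5))
  expect_true(all(is.finite(ds$f_p)))
  # cross-check one population against direct recomputation
  ms <- marker_stats(x)
  ms1 <- ms[ms$population == "pop1" & ms$maf > 0, ]
  expect_equal(ds$mean_ho[ds$population == "pop1"], mean(ms1$h_o))
  fi <- inbreeding_f(x)
  expect_equal(ds$mean_f[ds$population == "pop1"],
               mean(fi$f[fi$population == "pop1"]))
  tt <- t.test(fi$f[fi$population == "pop1"])
  expect_equal(ds$f_p[ds$population == "pop1"], tt$p.value)
})
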