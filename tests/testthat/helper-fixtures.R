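# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no binary fixtures exist.

# small hand-built cohort
toy_cohort <- function() {
  calls <- rbind(
    s1 = c(0L, 1L, 2L, NA),
    s2 = c(1L, 1L, 0L, 2L),
    s3 = c(2L, 0L, 1L, 1L))
  markers <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4"),
    chrom = c("1", "1", "2", "2"),
    pos_bp = c(100L, 5000L, 250L, 9000L),
    allele_a = "A", allele_b = "G")
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        population = c("p1", "p1", "p2"))
  geno_cohort(calls, markers, samples)
}

# random valid cohort with controlled missingness
random_cohort <- function(n = 10, m = 50, miss = 0, n_pop = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  if (miss > 0) calls[sample.int(n * m, round(miss * n * m))] <- NA_integer_
  chrom <- sort(sample(as.character(1:3), m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(1e6, length(ix)))), use.names = FALSE)
  markers <- data.frame(
    marker_id = sprintf("m%03d", seq_len(m)),
    chrom = chrom, pos_bp = pos,
    allele_a = "A", allele_b = "C")
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        population = rep(sprintf("pop%d", seq_len(n_pop)),
                                         length.out = n))
  geno_cohort(calls, markers, samples)
}

# Balding-Nichols two-population cohort with known divergence (for PCA)
bn_cohort <- function(n_per_pop = 30, m = 400, fst = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  shape <- (1 - fst) / fst
  calls <- NULL
  for (k in 1:2) {
    pk <- rbeta(m, p * shape, (1 - p) * shape)
    calls <- rbind(calls, matrix(rbinom(n_per_pop * m, 2L,
                                        rep(pk, each = n_per_pop)),
                                 nrow = n_per_pop))
  }
  markers <- data.frame(marker_id = sprintf("m%04d", seq_len(m)),
                        chrom = "1", pos_bp = seq_len(m) * 1000L,
                        allele_a = "A", allele_b = "T")
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(2 * n_per_pop)),
    population = rep(c("popA", "popB"), each = n_per_pop))
  geno_cohort(calls, markers, samples)
}

# independent brute-force oracle for the HWE exact test: enumerate every
# heterozygote count with the same allele counts, probabilities from the
# closed-form expression, p = sum of masses no more probable than observed
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa
  nb <- 2 * n_aa + n_Aa
  if (na == 0 || nb == 0) return(1)
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(na) - lfactorial(nb))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hs == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# direct-count r2 from phased haplotype pairs (oracle for EM on
# phase-resolved data)
r2_from_haplotypes <- function(hapA, hapB) {
  f11 <- mean(hapA == 0 & hapB == 0)
  f12 <- mean(hapA == 0 & hapB == 1)
  f21 <- mean(hapA == 1 & hapB == 0)
  f22 <- mean(hapA == 1 & hapB == 1)
  pa <- f11 + f12; pb <- f11 + f21
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den <= 0) return(0)
  (f11 * f22 - f12 * f21)^2 / den
}

# the standard constant-Ne validation simulation used by several checks
sved_sim <- function(seed, ne = 50, n_sample = 25, founder_markers = 4000,
                     bp_length = 5e7, morgans = 1, duration = 100,
                     maf_floor = 0.05) {
  cfg <- sim_config(seed = seed,
                    epochs = data.frame(duration = duration, ne = ne),
                    chromosomes = data.frame(chrom = "1",
                                             bp_length = bp_length,
                                             morgans = morgans),
                    n_markers = founder_markers, n_sample = n_sample,
                    maf_floor = maf_floor)
  simulate_cohort(cfg)
}

# helper: cohort of unrelated HWE genotypes plus one duplicate and one
# parent-offspring duo, genotypes drawn at known allele frequencies
related_cohort <- function(n_unrel = 60, m = 2000, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n_unrel * m, 2L, rep(p, each = n_unrel)),
                  nrow = n_unrel)
  # duplicate of sample 1
  dup <- calls[1, ]
  # child of sample 2: one gamete from the parent, one from the pool
  g_par <- calls[2, ]
  a1 <- ifelse(g_par == 0L, 0L,
        ifelse(g_par == 2L, 1L, rbinom(m, 1L, 0.5)))
  child <- a1 + rbinom(m, 1L, p)
  calls <- rbind(calls, dup, child)
  ids <- c(sprintf("u%03d", seq_len(n_unrel)), "dup1", "child2")
  geno_cohort(calls,
              data.frame(marker_id = sprintf("m%05d", seq_len(m)),
                         chrom = "1", pos_bp = seq_len(m) * 100L),
              data.frame(sample_id = ids, population = "p"))
}

# balanced two-population x two-chromosome design with a distance covariate
# whose values repeat identically in every cell (orthogonal to the factors)
balanced_records <- function(eff_pop = 0.1, eff_chr = 0.05, inter = 0.02,
                             slope = -1e-8, sigma = 0, n_cell = 30,
                             seed = 1) {
  set.seed(seed)
  base <- seq(1e4, 3e6, length.out = n_cell)
  d <- tidyr::expand_grid(population = c("A", "B"), chrom = c("1", "2"),
                          distance_bp = base)
  d$r2 <- 0.3 +
    eff_pop * (d$population == "B") +
    eff_chr * (d$chrom == "2") +
    inter * (d$population == "B" & d$chrom == "2") +
    slope * d$distance_bp +
    rnorm(nrow(d), 0, sigma)
  d
}

# textbook sequential sums of squares for the balanced orthogonal design
anova_oracle <- function(d) {
  y <- d$r2
  n <- length(y)
  gm <- mean(y)
  ss_pop <- sum(tapply(y, d$population, function(v) length(v) * (mean(v) - gm)^2))
  ss_chr <- sum(tapply(y, d$chrom, function(v) length(v) * (mean(v) - gm)^2))
  cellmean <- tapply(y, interaction(d$population, d$chrom), mean)
  cells <- interaction(d$population, d$chrom)
  popmean <- tapply(y, d$population, mean)[d$population]
  chrmean <- tapply(y, d$chrom, mean)[d$chrom]
  ss_int <- sum((cellmean[cells] - popmean - chrmean + gm)^2)
  # covariate after the factors: regression of cell-mean residuals on the
  # within-cell-centred covariate
  x <- d$distance_bp - tapply(d$distance_bp, cells, mean)[cells]
  resid_cells <- y - cellmean[cells]
  ss_cov <- sum(x * resid_cells)^2 / sum(x^2)
  ss_res <- sum(resid_cells^2) - ss_cov
  df <- c(pop = 1, chr = 1, int = 1, cov = 1,
          res = n - nlevels(cells) - 1)
  ms_res <- ss_res / df["res"]
  list(ss = c(pop = ss_pop, chr = ss_chr, int = ss_int, cov = ss_cov,
              res = ss_res),
       f = c(pop = ss_pop, chr = ss_chr, int = ss_int, cov = ss_cov) / ms_res,
       df = df)
}

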