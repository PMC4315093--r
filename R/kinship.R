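#' Method-of-moments IBD (PI_HAT) for all sample pairs
#'
#' Allele-frequency-conditioned method-of-moments estimator of the pairwise
#' identity-by-descent state probabilities P(IBD = 0, 1, 2), in the style of
#' the classic whole-genome SNP relatedness estimators: per marker, the
#' probabilities of observing IBS 0/1/2 given each IBD state follow from the
#' cohort allele frequencies; summing over the markers a pair shares gives a
#' linear system solved marker-set-wide, after which the three state
#' probabilities are truncated to \[0, 1\] and renormalised.
#' `PI_HAT = P(IBD=1)/2 + P(IBD=2)`.
#'
#' Monomorphic markers are ignored.  Frequencies are estimated from the
#' cohort supplied (markers are assumed to be MAF-filtered already).
#'
#' @param x A [geno_cohort()].
#' @param min_overlap Pairs sharing fewer non-missing markers than this are
#'   flagged unreliable (default 50).
#' @return Tibble with one row per unordered pair: `sample_1`, `sample_2`,
#'   `n_snps`, `k0`, `k1`, `k2`, `pi_hat`, `reliable`.
#' @export
kinship_ibd <- function(x, min_overlap = 50L) {
  g <- x$calls
  fr <- allele_freq(x)
  keep <- !is.na(fr$freq_b) & fr$freq_b > 0 & fr$freq_b < 1
  g <- g[, keep, drop = FALSE]
  p <- fr$freq_b[keep]
  q <- 1 - p
  n <- nrow(g)
  if (n < 2) abort("need at least two samples")

  I0 <- (!is.na(g) & g == 0L) * 1
  I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  M <- (!is.na(g)) * 1

  # joint genotype-pair counts via cross products (samples x samples)
  tI0 <- t(I0); tI1 <- t(I1); tI2 <- t(I2)
  N00 <- I0 %*% tI0; N01 <- I0 %*% tI1; N02 <- I0 %*% tI2
  N10 <- I1 %*% tI0; N11 <- I1 %*% tI1; N12 <- I1 %*% tI2
  N20 <- I2 %*% tI0; N21 <- I2 %*% tI1; N22 <- I2 %*% tI2

  ibs0 <- N02 + N20
  ibs1 <- N01 + N10 + N12 + N21
  ibs2 <- N00 + N11 + N22

  # per-marker P(IBS | IBD) from allele frequencies
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p * q
  e2_ibd1 <- 1 - e1_ibd1

  # expectation sums restricted to each pair's shared-marker set
  pairsum <- function(e) M %*% (e * t(M))
  E0_0 <- pairsum(e0_ibd0)
  E1_0 <- pairsum(e1_ibd0)
  E2_0 <- pairsum(e2_ibd0)
  E1_1 <- pairsum(e1_ibd1)
  E2_1 <- pairsum(e2_ibd1)
  Mshared <- M %*% t(M)

  P0 <- ibs0 / E0_0
  P1 <- (ibs1 - P0 * E1_0) / E1_1
  P2 <- (ibs2 - P0 * E2_0 - P1 * E2_1) / Mshared

  ut <- which(upper.tri(Mshared), arr.ind = TRUE)
  k <- cbind(P0[ut], P1[ut], P2[ut])
  k[!is.finite(k)] <- 0
  k[k < 0] <- 0
  k[k > 1] <- 1
  tot <- rowSums(k)
  tot[tot == 0] <- 1
  k <- k / tot

  ids <- x$samples$sample_id
  tibble::tibble(
    sample_1 = ids[ut[, 1]],
    sample_2 = ids[ut[, 2]],
    n_snps = as.integer(Mshared[ut]),
    k0 = k[, 1], k1 = k[, 2], k2 = k[, 3],
    pi_hat = k[, 2] / 2 + k[, 3],
    reliable = as.integer(Mshared[ut]) >= min_overlap
  )
}

#' Greedily drop related samples
#'
#' While any retained pair has kinship at or above `threshold`, the
#' highest-kinship offending pair is taken and the member with the larger
#' mean kinship to all other retained samples is removed (ties broken by
#' higher missingness, then by later lexicographic sample id).  The retained
#' set therefore contains no pair at or above the threshold.
#'
#' @param x A [geno_cohort()].
#' @param kinship Pairwise table from [kinship_ibd()].
#' @param threshold PI_HAT cut, default 0.45.
#' @return A `geno_cohort` without the removed samples; the removed ids are
#'   attached as attribute `"removed"`.
#' @export
drop_related <- function(x, kinship, threshold = 0.45) {
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- x$samples$sample_id
  kin <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  kin[cbind(kinship$sample_1, kinship$sample_2)] <- kinship$pi_hat
  kin[cbind(kinship$sample_2, kinship$sample_1)] <- kinship$pi_hat
  miss <- sample_missing_rate(x)
  missing <- stats::setNames(miss$missing_rate, miss$sample_id)

  keep <- ids
  removed <- character(0)
  repeat {
    sub <- kin[keep, keep, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- 0
    if (!length(sub) || max(sub) < threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(keep[w[1]], keep[w[2]])
    mk <- vapply(pair, function(s) mean(kin[s, setdiff(keep, s)]), numeric(1))
    drop <- if (mk[1] != mk[2]) {
      pair[which.max(mk)]
    } else if (missing[pair[1]] != missing[pair[2]]) {
      pair[which.max(missing[pair])]
    } else {
      max(pair)
    }
    removed <- c(removed, drop)
    keep <- setdiff(keep, drop)
  }
  out <- cohort_subset(x, sample_ids = keep)
  attr(out, "removed") <- removed
  out
}
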