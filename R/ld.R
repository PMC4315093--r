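#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' unphased diploid genotypes.  Every genotype combination except the double
#' heterozygote resolves its two gametes unambiguously; the EM iteration
#' splits the double heterozygotes between the coupling and repulsion phases
#' according to the current frequency estimates.  Initialisation is at
#' linkage equilibrium; convergence when the largest frequency change drops
#' below 1e-8 (at most 1000 iterations).
#'
#' Naming follows the conventional two-locus layout: alleles A1/A2 at the
#' first locus and B1/B2 at the second, with A1 = `allele_a` and A2 =
#' `allele_b` of the marker; `f11` is the frequency of haplotype A1B1, `f12`
#' of A1B2, `f21` of A2B1, `f22` of A2B2.
#'
#' @param g_a,g_b Integer vectors of per-individual allele_b counts (0/1/2,
#'   `NA` = missing) at the two loci.
#' @return Named numeric vector `c(f11, f12, f21, f22)` summing to 1, with
#'   attributes `iterations` and `converged`.
#' @export
#' @examples
#' haplotype_freqs_em(c(0, 1, 2, 2), c(0, 1, 2, 2))
haplotype_freqs_em <- function(g_a, g_b) {
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 2) abort("need at least 2 individuals called at both loci")
  g_a <- g_a[ok]; g_b <- g_b[ok]
  cnt <- vapply(0:2, function(i) vapply(0:2, function(j)
    sum(g_a == i & g_b == j), numeric(1)), numeric(3))
  # cnt[j+1, i+1] = count of (g_a = i, g_b = j)
  n <- list()
  for (i in 0:2) for (j in 0:2) n[[paste0("n", i, j)]] <- cnt[j + 1, i + 1]
  fit <- em_core(n$n00, n$n01, n$n02, n$n10, n$n11, n$n12,
                 n$n20, n$n21, n$n22)
  out <- c(f11 = fit$f_aa, f12 = fit$f_ab, f21 = fit$f_ba, f22 = fit$f_bb)
  attr(out, "iterations") <- fit$iterations
  attr(out, "converged") <- fit$converged
  out
}

# Vectorised EM over many locus pairs; the nij are vectors of genotype-pair
# counts with i = allele_b count at locus A, j = at locus B.  Haplotypes are
# labelled by the allele carried at (A, B): aa, ab, ba, bb.
em_core <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                    tol = 1e-8, max_iter = 1000L) {
  N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  two_n <- 2 * N
  # fixed (phase-resolved) gamete counts
  k_aa <- 2 * n00 + n01 + n10
  k_ab <- 2 * n02 + n01 + n12
  k_ba <- 2 * n20 + n10 + n21
  k_bb <- 2 * n22 + n21 + n12
  pa <- (k_ba + k_bb + n11) / two_n     # freq of allele_b at locus A
  pb <- (k_ab + k_bb + n11) / two_n
  f_aa <- (1 - pa) * (1 - pb)
  f_ab <- (1 - pa) * pb
  f_ba <- pa * (1 - pb)
  f_bb <- pa * pb
  iter <- 0L
  repeat {
    iter <- iter + 1L
    den <- f_aa * f_bb + f_ab * f_ba
    pi_coup <- ifelse(den > 0, f_aa * f_bb / den, 0.5)
    new_aa <- (k_aa + n11 * pi_coup) / two_n
    new_bb <- (k_bb + n11 * pi_coup) / two_n
    new_ab <- (k_ab + n11 * (1 - pi_coup)) / two_n
    new_ba <- (k_ba + n11 * (1 - pi_coup)) / two_n
    delta <- pmax(abs(new_aa - f_aa), abs(new_ab - f_ab),
                  abs(new_ba - f_ba), abs(new_bb - f_bb))
    f_aa <- new_aa; f_ab <- new_ab; f_ba <- new_ba; f_bb <- new_bb
    if (all(delta < tol) || iter >= max_iter) break
  }
  list(f_aa = f_aa, f_ab = f_ab, f_ba = f_ba, f_bb = f_bb,
       iterations = iter, converged = all(delta < tol))
}

#' Squared allelic correlation from haplotype frequencies
#'
#' \eqn{r^2 = (f_{11} f_{22} - f_{12} f_{21})^2 / (f_{A1} f_{A2} f_{B1} f_{B2})},
#' clipped to \[0, 1\] against floating error.  If either locus is
#' monomorphic (a zero marginal), \eqn{r^2} is 0 by convention.
#'
#' @param f11,f12,f21,f22 Haplotype frequencies (vectors allowed) summing
#'   to 1.
#' @return Numeric vector of r-squared values.
#' @export
#' @examples
#' r2_pair(0.4, 0.1, 0.1, 0.4)  # 0.36
r2_pair <- function(f11, f12, f21, f22) {
  fa1 <- f11 + f12
  fa2 <- f21 + f22
  fb1 <- f11 + f21
  fb2 <- f12 + f22
  den <- fa1 * fa2 * fb1 * fb2
  d <- f11 * f22 - f12 * f21
  out <- ifelse(den > 0, d * d / den, 0)
  pmin(pmax(out, 0), 1)
}

#' Within-chromosome pairwise r-squared scan
#'
#' Computes EM-based \eqn{r^2} for every marker pair on the same chromosome
#' that falls within BOTH windows: at most `window_snps` markers apart (index
#' difference) and at most `window_kb` kilobases apart.  All values are
#' reported (no default 0.2 floor); records are ordered by chromosome, then
#' left marker position, then right marker position.
#'
#' Chromosomes with fewer than two markers are skipped (with a message).
#' Pairs with fewer than two individuals called at both loci are dropped.
#'
#' @param x A [geno_cohort()] (typically after LD-regime QC, one population).
#' @param window_snps Maximum index separation (default 5000).
#' @param window_kb Maximum physical separation in kb (default 10000).
#' @param report_min Only report pairs with `r2 >= report_min` (default 0).
#' @return Tibble of class `popld_ld` with columns `population`, `chrom`,
#'   `marker_a`, `marker_b`, `pos_a`, `pos_b`, `distance_bp`, `n_ind`, `r2`.
#' @export
ld_scan <- function(x, window_snps = 5000L, window_kb = 10000, report_min = 0) {
  pops <- unique(x$samples$population)
  pop_label <- if (length(pops) == 1L) pops else "all"
  res <- list()
  for (chr in unique(x$markers$chrom)) {
    sel <- x$markers$chrom == chr
    if (sum(sel) < 2) {
      inform(sprintf("ld_scan: chromosome %s has <2 markers, skipped", chr))
      next
    }
    mk <- x$markers[sel, ]
    g <- x$calls[, sel, drop = FALSE]
    pr <- window_pairs(mk$pos_bp, window_snps, window_kb * 1000)
    if (!nrow(pr)) next
    r2 <- r2_pairs_genotypes(g, pr[, 1], pr[, 2])
    res[[chr]] <- tibble::tibble(
      population = pop_label,
      chrom = chr,
      marker_a = mk$marker_id[pr[, 1]],
      marker_b = mk$marker_id[pr[, 2]],
      pos_a = mk$pos_bp[pr[, 1]],
      pos_b = mk$pos_bp[pr[, 2]],
      distance_bp = mk$pos_bp[pr[, 2]] - mk$pos_bp[pr[, 1]],
      n_ind = r2$n_ind,
      r2 = r2$r2
    )
  }
  out <- if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    population = character(), chrom = character(),
    marker_a = character(), marker_b = character(),
    pos_a = integer(), pos_b = integer(), distance_bp = integer(),
    n_ind = integer(), r2 = numeric())
  out <- out[out$n_ind >= 2 & out$r2 >= report_min, ]
  class(out) <- c("popld_ld", class(out))
  out
}

# index pairs (i, j), i < j, j - i <= max_sep, pos[j] - pos[i] <= max_bp
window_pairs <- function(pos, max_sep, max_bp) {
  L <- length(pos)
  is <- js <- list()
  for (i in seq_len(L - 1)) {
    jmax <- min(L, i + max_sep)
    # furthest j with pos[j] <= pos[i] + max_bp
    jmax <- min(jmax, findInterval(pos[i] + max_bp, pos))
    if (jmax > i) {
      is[[i]] <- rep.int(i, jmax - i)
      js[[i]] <- seq.int(i + 1L, jmax)
    }
  }
  out <- cbind(unlist(is), unlist(js))
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# vectorised EM r2 for arbitrary column pairs of a genotype matrix
r2_pairs_genotypes <- function(g, ia, ib, chunk = 50000L) {
  I0 <- (!is.na(g) & g == 0L) * 1
  I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  P <- length(ia)
  r2 <- numeric(P)
  n_ind <- integer(P)
  for (start in seq(1L, P, by = chunk)) {
    idx <- start:min(P, start + chunk - 1L)
    a <- ia[idx]; b <- ib[idx]
    n <- list()
    for (i in 0:2) for (j in 0:2) {
      Ia <- list(I0, I1, I2)[[i + 1]]
      Ib <- list(I0, I1, I2)[[j + 1]]
      n[[paste0("n", i, j)]] <- colSums(Ia[, a, drop = FALSE] *
                                        Ib[, b, drop = FALSE])
    }
    fit <- em_core(n$n00, n$n01, n$n02, n$n10, n$n11, n$n12,
                   n$n20, n$n21, n$n22)
    r2[idx] <- r2_pair(fit$f_aa, fit$f_ab, fit$f_ba, fit$f_bb)
    n_ind[idx] <- as.integer(n$n00 + n$n01 + n$n02 + n$n10 + n$n11 +
                             n$n12 + n$n20 + n$n21 + n$n22)
  }
  list(r2 = r2, n_ind = n_ind)
}
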