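#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for a biallelic marker: conditioning on the observed
#' allele counts, the p-value is the summed probability of every heterozygote
#' count whose probability does not exceed that of the observed configuration
#' (probability-mass ordering).  Probabilities follow the exact distribution
#' of heterozygote counts under random union of gametes; they are computed by
#' the stable two-term recurrence
#' \deqn{P(h+2)/P(h) = 4 n_{AA}(h) n_{aa}(h) / ((h+1)(h+2)).}
#' "Does not exceed" is evaluated with a relative tolerance of 1e-10 so that
#' ties are handled identically regardless of how the masses are computed.
#'
#' Vectorised over the three counts.  A monomorphic marker returns 1 (no test
#' possible).
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (recycled to a common
#'   length); each total must be positive.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)   # modal configuration, p = 1
#' hwe_exact_p(50, 0, 50)    # complete heterozygote deficit
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  k <- vctrs_recycle(n_AA, n_Aa, n_aa)
  n_AA <- k[[1]]; n_Aa <- k[[2]]; n_aa <- k[[3]]
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) abort("counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) abort("total genotype count must be positive")
  na <- 2L * n_AA + n_Aa                   # copies of allele A
  nb <- 2L * n_aa + n_Aa
  out <- rep(1, length(n))
  poly <- na > 0L & nb > 0L
  if (!any(poly)) return(out)

  key <- paste(n[poly], pmin(na, nb)[poly])
  idx <- split(which(poly), key)
  for (grp in idx) {
    tot <- n[grp[1]]
    rare <- min(na[grp[1]], nb[grp[1]])
    dist <- hwe_het_distribution(tot, rare)
    p_obs <- dist[as.character(n_Aa[grp])]
    # sum of masses no more probable than observed, with relative tie tolerance
    out[grp] <- vapply(p_obs, function(p0) {
      min(1, sum(dist[dist <= p0 * (1 + 1e-10)]))
    }, numeric(1))
  }
  out
}

# Exact distribution of the heterozygote count given total genotypes `n` and
# rare-allele count `na`; names are heterozygote counts.
hwe_het_distribution <- function(n, na) {
  nb <- 2L * n - na
  hs <- seq.int(na %% 2L, min(na, nb), by = 2L)
  if (length(hs) == 1L) {
    out <- 1
    names(out) <- hs
    return(out)
  }
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    lp[i] <- lp[i - 1] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- hs
  p
}

# minimal common-length recycling for scalar-or-vector args
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else if (length(x) == 1L) rep(x, n)
    else abort("arguments must have length 1 or a common length")
  })
}
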