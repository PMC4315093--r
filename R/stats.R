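#' Per-marker diversity statistics
#'
#' For each marker (within one population, or per population): minor allele
#' frequency, observed heterozygosity (fraction of heterozygotes among
#' non-missing calls) and expected heterozygosity under Hardy-Weinberg
#' proportions with the small-sample correction
#' \eqn{H_E = 2\hat p(1-\hat p)\, n/(n-1)} where n is the non-missing
#' chromosomal count.  All-missing markers are excluded (and counted in the
#' `n_excluded` attribute).
#'
#' @param x A [geno_cohort()].
#' @param by_population Compute within each population (default `TRUE`).
#' @param correct_he Apply the n/(n-1) small-sample correction (default
#'   `TRUE`).
#' @return Tibble with `population` (if grouped), `marker_id`, `n_called`,
#'   `freq_b`, `maf`, `h_o`, `h_e`.
#' @export
marker_stats <- function(x, by_population = TRUE, correct_he = TRUE) {
  pops <- if (by_population) unique(x$samples$population) else NA_character_
  res <- lapply(pops, function(pop) {
    g <- if (is.na(pop)) x$calls else
      x$calls[x$samples$population == pop, , drop = FALSE]
    n_called <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    h_o <- colSums(g == 1L, na.rm = TRUE) / pmax(n_called, 1L)
    nchr <- 2 * n_called
    corr <- if (correct_he) ifelse(nchr > 1, nchr / (nchr - 1), 1) else 1
    h_e <- 2 * p * (1 - p) * corr
    out <- tibble::tibble(marker_id = x$markers$marker_id,
                          n_called = as.integer(unname(n_called)),
                          freq_b = unname(p), maf = unname(pmin(p, 1 - p)),
                          h_o = unname(h_o), h_e = unname(h_e))
    if (!is.na(pop)) out <- dplyr::mutate(out, population = pop,
                                          .before = 1)
    out[n_called > 0, ]
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_excluded") <- length(pops) * n_markers(x) - nrow(out)
  out
}

#' Per-individual inbreeding coefficient F (homozygosity method)
#'
#' \eqn{F = (O_{hom} - E_{hom}) / (L - E_{hom})}, where over the
#' individual's non-missing markers \eqn{O_{hom}} is the observed
#' homozygote count and \eqn{E_{hom} = \sum_i (1 - 2 p_i q_i\, n_i/(n_i-1))}
#' the count expected under Hardy-Weinberg proportions at the population
#' allele frequencies.  Individuals with fewer than `min_markers` non-missing
#' calls are flagged unreliable.
#'
#' @param x A [geno_cohort()].
#' @param min_markers Reliability floor, default 100.
#' @return Tibble with `sample_id`, `population`, `n_markers`, `o_hom`,
#'   `e_hom`, `f`, `reliable`.
#' @export
inbreeding_f <- function(x, min_markers = 100L) {
  res <- lapply(unique(x$samples$population), function(pop) {
    sel <- x$samples$population == pop
    g <- x$calls[sel, , drop = FALSE]
    n_called <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    nchr <- 2 * n_called
    exp_het <- ifelse(nchr > 1, 2 * p * (1 - p) * nchr / (nchr - 1), 0)
    hom_exp_marker <- 1 - exp_het
    M <- !is.na(g)
    o_hom <- rowSums(M & g != 1L)
    e_hom <- as.numeric(M %*% hom_exp_marker)
    L <- rowSums(M)
    f <- ifelse(L - e_hom != 0, (o_hom - e_hom) / (L - e_hom), 0)
    tibble::tibble(sample_id = x$samples$sample_id[sel], population = pop,
                   n_markers = as.integer(unname(L)), o_hom = unname(o_hom),
                   e_hom = unname(e_hom), f = unname(f),
                   reliable = unname(L >= min_markers))
  })
  dplyr::bind_rows(res)
}

#' Per-population diversity summary
#'
#' One row per population with means and SDs of the per-marker MAF, observed
#' and expected heterozygosity over polymorphic markers, the mean
#' per-individual inbreeding coefficient F with its SD, a one-sample t-test
#' of F against zero, and the ratio-based alternative `f_ratio = 1 -
#' mean(H_O)/mean(H_E)` for comparison.
#'
#' @param x A [geno_cohort()].
#' @return Tibble with one row per population.
#' @export
diversity_summary <- function(x) {
  ms <- marker_stats(x) |> dplyr::filter(.data$maf > 0)
  fi <- inbreeding_f(x)
  msum <- ms |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     mean_maf = mean(.data$maf), sd_maf = stats::sd(.data$maf),
                     mean_ho = mean(.data$h_o), sd_ho = stats::sd(.data$h_o),
                     mean_he = mean(.data$h_e), sd_he = stats::sd(.data$h_e),
                     .groups = "drop")
  fsum <- fi |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      mean_f = mean(.data$f), sd_f = stats::sd(.data$f),
      f_t = if (dplyr::n() > 1 && stats::sd(.data$f) > 0)
        stats::t.test(.data$f)$statistic else NA_real_,
      f_p = if (dplyr::n() > 1 && stats::sd(.data$f) > 0)
        stats::t.test(.data$f)$p.value else NA_real_,
      .groups = "drop")
  out <- dplyr::left_join(msum, fsum, by = "population") |>
    dplyr::mutate(f_ratio = 1 - .data$mean_ho / .data$mean_he)
  class(out) <- c("popld_diversity", class(out))
  out
}

#' Minor-allele-frequency spectrum
#'
#' Proportion of polymorphic markers per MAF bin.  Bins are
#' `[0, 0.05], (0.05, 0.1], (0.1, 0.2], (0.2, 0.3], (0.3, 0.4], (0.4, 0.5]`
#' (left-open/right-closed, first bin closed at 0); proportions are over
#' polymorphic markers and sum to 1.
#'
#' @param x A [geno_cohort()], or a numeric vector of MAFs.
#' @param bin_edges MAF bin edges, default `c(0, 0.05, 0.1, 0.2, 0.3, 0.4,
#'   0.5)`.
#' @param by_population Compute per population (default `FALSE`: pooled
#'   cohort frequencies).
#' @return Tibble of class `popld_maf_spectrum` with (`population`,)
#'   `bin_lower`, `bin_upper`, `n_markers`, `proportion`.
#' @export
maf_spectrum <- function(x, bin_edges = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                         by_population = FALSE) {
  one <- function(maf, pop = NULL) {
    maf <- maf[!is.na(maf) & maf > 0]
    if (!length(maf)) warn("no polymorphic markers; spectrum is all zero")
    b <- cut(maf, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
    n <- as.integer(table(b))
    out <- tibble::tibble(
      bin_lower = bin_edges[-length(bin_edges)],
      bin_upper = bin_edges[-1],
      n_markers = n,
      proportion = if (sum(n)) n / sum(n) else rep(0, length(n)))
    if (!is.null(pop)) out <- dplyr::mutate(out, population = pop, .before = 1)
    out
  }
  if (is.numeric(x)) {
    out <- one(x)
  } else if (by_population) {
    out <- dplyr::bind_rows(lapply(unique(x$samples$population), function(p)
      one(allele_freq(x, p)$maf, p)))
  } else {
    out <- one(allele_freq(x)$maf)
  }
  class(out) <- c("popld_maf_spectrum", class(out))
  out
}

#' Principal component analysis of genotypes
#'
#' Markers are centred by twice the allele frequency and scaled by
#' \eqn{\sqrt{2\hat p(1-\hat p)}}; missing calls are imputed to the marker
#' mean (i.e. zero after centring); monomorphic markers are dropped.  The
#' decomposition is the eigendecomposition of the sample-by-sample
#' covariance of the standardised matrix (the genomic relationship matrix
#' \eqn{XX^T/L}).  Components are ordered by eigenvalue; each component's
#' sign is fixed so its largest-magnitude marker loading is positive.
#'
#' @param x A [geno_cohort()].
#' @param k Number of components to return (default 10, truncated to the
#'   available rank with a warning).
#' @return Tibble of class `popld_pca` with `sample_id`, `population`,
#'   `PC1..PCk`; eigenvalues and the proportion of variance explained are
#'   attached as attributes `eigenvalues`, `var_explained`.
#' @export
pca_genotypes <- function(x, k = 10L) {
  fr <- allele_freq(x)
  keep <- !is.na(fr$freq_b) & fr$freq_b > 0 & fr$freq_b < 1
  g <- x$calls[, keep, drop = FALSE]
  p <- fr$freq_b[keep]
  X <- sweep(g, 2, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  L <- ncol(X)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-8
  rank <- sum(pos)
  if (k > rank) {
    warn(sprintf("requested %d components but rank is %d; truncating", k, rank))
    k <- rank
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  D <- sv$d[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(D, k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  eig <- sv$d^2 / L   # eigenvalues of XX^T / L
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = x$samples$sample_id,
                   population = x$samples$population),
    tibble::as_tibble(scores))
  attr(out, "eigenvalues") <- eig
  attr(out, "var_explained") <- eig / sum(eig)
  class(out) <- c("popld_pca", class(out))
  out
}
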