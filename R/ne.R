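#' Sample-size adjustment of r-squared
#'
#' Subtracts the finite-sample expectation under linkage equilibrium,
#' \eqn{r^2_{adj} = r^2 - 1/(2n)}, where `n` is the chromosomal sample size
#' (twice the number of diploid individuals).  Negative adjusted values are
#' floored at 0 and flagged via the `"floored"` attribute.
#'
#' @param r2 Numeric vector of r-squared values.
#' @param n Chromosomal sample size (>= 2).
#' @return Numeric vector with attribute `floored` (logical vector).
#' @export
#' @examples
#' adjust_r2(0.30, 58)  # 0.30 - 1/116
adjust_r2 <- function(r2, n) {
  if (any(n < 2)) abort("domain error: chromosomal sample size must be >= 2")
  raw <- r2 - 1 / (2 * n)
  out <- pmax(raw, 0)
  attr(out, "floored") <- raw < 0
  out
}

#' Convert physical to genetic distance
#'
#' Linear conversion \eqn{c = \bar o_{chr} \times d_{bp}} using the
#' chromosome's mean recombination rate (Morgans per bp) from a
#' [recomb_map()]; additive over sub-intervals.
#'
#' @param distance_bp Physical distances (bp).
#' @param chrom Chromosome label(s), recycled against `distance_bp`.
#' @param rmap A [recomb_map()] tibble.
#' @return Genetic distances in Morgans.
#' @export
physical_to_genetic <- function(distance_bp, chrom, rmap) {
  idx <- match(as.character(chrom), rmap$chrom)
  if (anyNA(idx)) {
    abort(sprintf("lookup error: chromosome(s) %s not in recombination map",
                  paste(unique(chrom[is.na(idx)]), collapse = ", ")))
  }
  rmap$morgans_per_bp[idx] * distance_bp
}

#' Effective population size from a distance bin
#'
#' Inverts the drift-recombination expectation
#' \eqn{E[r^2_{adj}] = 1/(\alpha + 4 N_e c)} to
#' \eqn{N_e = (1/r^2_{adj} - \alpha) / (4c)}; `alpha = 1` assumes no
#' mutation, `alpha = 2` accounts for it.
#'
#' @param r2_adj Mean adjusted r-squared in the bin; must lie in
#'   `(0, 1/alpha)` (otherwise `NA` is returned).
#' @param c_morgans Mean recombination distance of the bin (Morgans, > 0).
#' @param alpha 1 (default, no mutation) or 2.
#' @return Ne estimate(s); `NA` where undefined.
#' @export
#' @examples
#' ne_from_bin(0.25, 0.01)      # 75
#' ne_from_bin(1 / 3, 0.005)    # 100
ne_from_bin <- function(r2_adj, c_morgans, alpha = 1) {
  stopifnot(all(alpha %in% c(1, 2)))
  ok <- !is.na(r2_adj) & r2_adj > 0 & r2_adj < 1 / alpha &
    !is.na(c_morgans) & c_morgans > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- (1 / r2_adj[ok] - alpha) / (4 * c_morgans[ok])
  out
}

#' LD-based effective population size trajectory
#'
#' Bins pairwise LD records by physical distance (same conventions as
#' [decay_curve()]), converts each pair's distance to Morgans via the
#' recombination map, adjusts each pair's r-squared for sample size, and for
#' each bin inverts the mean adjusted r-squared at the mean genetic distance
#' to an Ne estimate referring to \eqn{t = 1/(2\bar c)} generations ago.
#' Larger distance bins map to more recent generations.  Empty or
#' out-of-domain bins are omitted (with a message).
#'
#' @param records Tibble from [ld_scan()].
#' @param rmap A [recomb_map()].
#' @param n_chromosomal Chromosomal sample size (2 x diploid individuals)
#'   of the population the records come from.
#' @param bin_edges_kb Upper bin edges (kb), default as in [decay_curve()].
#' @param alpha 1 (default) or 2, see [ne_from_bin()].
#' @param c_mode `"per_pair"` (default: per-bin c is the mean of per-pair
#'   conversions) or `"midpoint"` (bin midpoint converted with the
#'   pair-count-weighted mean chromosome rate).
#' @return Tibble of class `popld_ne` sorted by `t_generations` ascending:
#'   (`population`,) `bin_lower_kb`, `bin_upper_kb`, `n_pairs`,
#'   `mean_c_morgans`, `t_generations`, `mean_r2_adj`, `ne`.
#' @export
ne_trajectory <- function(records, rmap, n_chromosomal,
                          bin_edges_kb = c(10, 20, 40, 60, 100, 200, 500,
                                           1000, 2000, 5000),
                          alpha = 1, c_mode = c("per_pair", "midpoint")) {
  c_mode <- match.arg(c_mode)
  stopifnot(!is.unsorted(bin_edges_kb, strictly = TRUE))
  edges <- c(0, bin_edges_kb)
  grp <- intersect("population", names(records))

  d <- records |>
    dplyr::mutate(
      c_pair = physical_to_genetic(.data$distance_bp, .data$chrom, rmap),
      r2_adj = as.numeric(adjust_r2(.data$r2, n_chromosomal)),
      .bin = cut(.data$distance_bp / 1000, breaks = edges, right = TRUE))
  d <- d[!is.na(d$.bin), ]

  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, ".bin")))) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_c_morgans = if (c_mode == "per_pair") mean(.data$c_pair) else
        mean(.data$c_pair / .data$distance_bp) *
          mean(edges[as.integer(.data$.bin[1]) + 0:1]) * 1000,
      mean_r2_adj = mean(.data$r2_adj),
      .groups = "drop") |>
    dplyr::mutate(
      bin_lower_kb = edges[as.integer(.data$.bin)],
      bin_upper_kb = edges[as.integer(.data$.bin) + 1L],
      t_generations = 1 / (2 * .data$mean_c_morgans),
      ne = ne_from_bin(.data$mean_r2_adj, .data$mean_c_morgans, alpha))
  bad <- is.na(out$ne)
  if (any(bad)) {
    inform(sprintf("ne_trajectory: %d bin(s) skipped (empty or r2_adj outside (0, 1/alpha))",
                   sum(bad)))
  }
  out <- out[!bad, c(grp, "bin_lower_kb", "bin_upper_kb", "n_pairs",
                     "mean_c_morgans", "t_generations", "mean_r2_adj", "ne")]
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(c(grp, "t_generations"))))
  class(out) <- c("popld_ne", class(out))
  out
}
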