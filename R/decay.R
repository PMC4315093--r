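#' Distance-binned LD decay curve
#'
#' Groups pairwise r-squared records into consecutive distance intervals and
#' reports the mean and SD per bin.  Bins are half-open `(lower, upper]` in
#' kb, with the first bin `(0, edges[1]]`; the default edges are 10, 20, 40,
#' 60, 100, 200, 500, 1000, 2000 and 5000 kb (extendable to 10000 kb for
#' macro-chromosome analyses).  Empty bins are reported with a zero pair
#' count.
#'
#' If the record table carries a `population` column the curve is computed
#' per population; set `by_chromosome = TRUE` for per-chromosome curves.
#'
#' @param records Tibble from [ld_scan()] (needs `distance_bp`, `r2`).
#' @param bin_edges_kb Ascending upper bin edges in kb.
#' @param by_chromosome Also group by chromosome (default `FALSE`).
#' @return Tibble of class `popld_decay` with columns (`population`,)
#'   (`chrom`,) `bin_lower_kb`, `bin_upper_kb`, `n_pairs`, `mean_r2`, `sd_r2`.
#' @export
decay_curve <- function(records,
                        bin_edges_kb = c(10, 20, 40, 60, 100, 200, 500,
                                         1000, 2000, 5000),
                        by_chromosome = FALSE) {
  stopifnot(!is.unsorted(bin_edges_kb, strictly = TRUE), all(bin_edges_kb > 0))
  edges <- c(0, bin_edges_kb)
  grp <- character(0)
  if ("population" %in% names(records)) grp <- c(grp, "population")
  if (by_chromosome) grp <- c(grp, "chrom")

  records <- dplyr::mutate(
    records,
    .bin = cut(.data$distance_bp / 1000, breaks = edges, right = TRUE))
  records <- records[!is.na(records$.bin), ]

  skel <- tidyr::expand_grid(
    !!!c(lapply(grp, function(g) unique(records[[g]])) |>
           stats::setNames(grp),
         list(.bin = factor(levels(records$.bin),
                            levels = levels(records$.bin)))))

  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, ".bin")))) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_r2 = mean(.data$r2),
                     sd_r2 = stats::sd(.data$r2),
                     .groups = "drop") |>
    dplyr::right_join(skel, by = c(grp, ".bin")) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
                  bin_lower_kb = edges[as.integer(.data$.bin)],
                  bin_upper_kb = edges[as.integer(.data$.bin) + 1L]) |>
    dplyr::select(dplyr::all_of(grp), "bin_lower_kb", "bin_upper_kb",
                  "n_pairs", "mean_r2", "sd_r2") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "bin_lower_kb"))))
  class(out) <- c("popld_decay", class(out))
  out
}

#' Per-chromosome mean r-squared summary
#'
#' The chromosome-level LD table: mean and SD of the windowed pairwise
#' r-squared per chromosome (and per population when the column is present).
#'
#' @param records Tibble from [ld_scan()].
#' @return Tibble with (`population`,) `chrom`, `n_pairs`, `mean_r2`, `sd_r2`.
#' @export
ld_chromosome_summary <- function(records) {
  grp <- intersect(c("population", "chrom"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_r2 = mean(.data$r2),
                     sd_r2 = stats::sd(.data$r2),
                     .groups = "drop")
}
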