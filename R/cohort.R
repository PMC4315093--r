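#' Genotype cohort container
#'
#' Bundles a diploid call matrix (samples x markers, values 0/1/2 counting
#' copies of `allele_b`, `NA` = missing), a marker map and a sample table into
#' a single validated object.  All downstream statistics operate on this
#' container and return tibbles.
#'
#' Markers are stored sorted by chromosome then base-pair position; positions
#' are 1-based and must be strictly increasing within a chromosome.
#'
#' @param calls Integer matrix, samples in rows, markers in columns.  Row
#'   names (if present) must match `samples$sample_id`, column names
#'   `markers$marker_id`.
#' @param markers Data frame with columns `marker_id`, `chrom` (character:
#'   `"1"`..`"28"`, `"Z"`, `"W"`, `"0"`/`"unmapped"`, or a linkage-group
#'   label), `pos_bp`, and optionally `allele_a`, `allele_b`.
#' @param samples Data frame with columns `sample_id` and `population`.
#'
#' @return An object of class `geno_cohort`: a list with elements `calls`,
#'   `markers` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'                 dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' markers <- data.frame(marker_id = c("m1", "m2"), chrom = "1",
#'                       pos_bp = c(100L, 200L),
#'                       allele_a = "A", allele_b = "G")
#' samples <- data.frame(sample_id = c("s1", "s2"), population = "popA")
#' geno_cohort(calls, markers, samples)
geno_cohort <- function(calls, markers, samples) {
  markers <- tibble::as_tibble(markers)
  samples <- tibble::as_tibble(samples)
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  if (!all(c("marker_id", "chrom", "pos_bp") %in% names(markers))) {
    abort("`markers` needs columns marker_id, chrom, pos_bp.")
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    abort("`samples` needs columns sample_id, population.")
  }
  markers$chrom <- as.character(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  if (!"allele_a" %in% names(markers)) markers$allele_a <- "A"
  if (!"allele_b" %in% names(markers)) markers$allele_b <- "B"
  if (anyDuplicated(markers$marker_id)) abort("duplicate marker_id in map")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (nrow(markers) != ncol(calls)) {
    abort(sprintf("dimension error: %d markers in map but %d call columns",
                  nrow(markers), ncol(calls)))
  }
  if (nrow(samples) != nrow(calls)) {
    abort(sprintf("dimension error: %d samples but %d call rows",
                  nrow(samples), nrow(calls)))
  }
  cn <- colnames(calls)
  if (!is.null(cn) && !identical(cn, markers$marker_id) &&
      setequal(cn, markers$marker_id) && !anyDuplicated(cn)) {
    calls <- calls[, markers$marker_id, drop = FALSE]
  }
  if (any(!is.na(calls) & (calls < 0L | calls > 2L))) {
    abort("calls must be 0, 1, 2 or NA")
  }
  if (any(markers$pos_bp < 0L, na.rm = TRUE)) abort("pos_bp must be non-negative")
  ord <- order(chrom_rank(markers$chrom), markers$pos_bp)
  markers <- markers[ord, ]
  calls <- calls[, ord, drop = FALSE]
  dup <- stats::ave(markers$pos_bp, markers$chrom,
                    FUN = function(x) duplicated(x))
  if (any(dup == 1)) {
    abort("positions must be strictly increasing within a chromosome")
  }
  dimnames(calls) <- list(samples$sample_id, markers$marker_id)
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "geno_cohort")
}

# stable ordering: autosomes numerically, then Z, W, linkage groups, unmapped
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(n), n,
          ifelse(chrom == "Z", 100,
          ifelse(chrom == "W", 101,
          ifelse(chrom %in% c("0", "unmapped"), 999, 200))))
  rank + match(chrom, sort(unique(chrom))) / 1e6
}

#' Classify chromosome labels
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector with values `"autosome"`, `"sex"`, `"unmapped"`
#'   or `"linkage_group"`.
#' @export
chrom_class <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(chrom %in% as.character(1:28), "autosome",
  ifelse(chrom %in% c("Z", "W"), "sex",
  ifelse(chrom %in% c("0", "unmapped", "NA"), "unmapped", "linkage_group")))
}

#' @export
print.geno_cohort <- function(x, ...) {
  cat(sprintf("<geno_cohort> %d samples x %d markers, %d population(s)\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$samples$population))))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$markers$chrom), collapse = " ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @rdname geno_cohort
#' @param x A `geno_cohort`.
#' @export
n_markers <- function(x) ncol(x$calls)

#' @rdname geno_cohort
#' @export
n_samples <- function(x) nrow(x$calls)

#' Subset a cohort by marker and/or sample identifiers
#'
#' @param x A [geno_cohort()].
#' @param marker_ids,sample_ids Character vectors of identifiers to keep
#'   (`NULL` keeps all).
#' @return A `geno_cohort`.
#' @export
cohort_subset <- function(x, marker_ids = NULL, sample_ids = NULL) {
  mk <- if (is.null(marker_ids)) x$markers$marker_id else marker_ids
  sk <- if (is.null(sample_ids)) x$samples$sample_id else sample_ids
  keep_m <- x$markers$marker_id %in% mk
  keep_s <- x$samples$sample_id %in% sk
  geno_cohort(x$calls[keep_s, keep_m, drop = FALSE],
              x$markers[keep_m, ], x$samples[keep_s, ])
}

#' Per-marker and per-sample missingness
#'
#' @param x A [geno_cohort()].
#' @return A tibble: `marker_missing_rate()` has columns `marker_id`,
#'   `missing_rate`; `sample_missing_rate()` has `sample_id`, `missing_rate`.
#' @export
marker_missing_rate <- function(x) {
  tibble::tibble(marker_id = x$markers$marker_id,
                 missing_rate = unname(colMeans(is.na(x$calls))))
}

#' @rdname marker_missing_rate
#' @export
sample_missing_rate <- function(x) {
  tibble::tibble(sample_id = x$samples$sample_id,
                 missing_rate = unname(rowMeans(is.na(x$calls))))
}

#' Allele-B frequency and minor allele frequency per marker
#'
#' Frequencies are computed over non-missing calls of the samples in the
#' cohort (optionally restricted to one population).
#'
#' @param x A [geno_cohort()].
#' @param population Optional population label to restrict to.
#' @return Tibble with `marker_id`, `n_called` (diploid individuals),
#'   `freq_b`, `maf`.
#' @export
allele_freq <- function(x, population = NULL) {
  g <- x$calls
  if (!is.null(population)) {
    g <- g[x$samples$population %in% population, , drop = FALSE]
  }
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  p[n_called == 0] <- NA_real_
  tibble::tibble(marker_id = x$markers$marker_id,
                 n_called = as.integer(unname(n_called)),
                 freq_b = unname(p),
                 maf = unname(pmin(p, 1 - p)))
}

#' Population panel summary
#'
#' One row per population with the diploid and chromosomal sample sizes used
#' by the sample-size adjustment of r-squared.
#'
#' @param x A [geno_cohort()].
#' @return Tibble with `population`, `n_individuals`, `n_chromosomal`.
#' @export
population_panel <- function(x) {
  x$samples |>
    dplyr::count(.data$population, name = "n_individuals") |>
    dplyr::mutate(n_chromosomal = 2L * .data$n_individuals)
}
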