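#' Quality-control configuration
#'
#' Thresholds for the staged marker/sample filters.  Two named presets match
#' the two regimes used in SNP-array surveys of this kind:
#'
#' * `"structure"` — for population-structure analyses: drop sex-chromosome
#'   and unmapped markers, markers with >5% missingness, monomorphic markers
#'   and MAF <= 0.02; drop samples with >5% missingness and one member of
#'   each pair with kinship >= 0.45; LD-prune at r2 >= 0.2.  No HWE filter.
#' * `"ld"` — per-population LD/Ne analyses: as above but MAF <= 0.05, an
#'   exact-test HWE filter at P <= 0.001, and no LD pruning.
#'
#' MAF thresholds are exclusive-of-equal removal rules: a marker is removed
#' when `maf <= maf_min` and kept when strictly above.
#'
#' @param maf_min Remove markers with MAF at or below this (0 disables the
#'   MAF stage beyond the monomorphic stage).
#' @param hwe_p_min Remove markers with HWE exact p at or below this
#'   (`NA` disables).
#' @param marker_missing_max Remove markers with missingness above this.
#' @param sample_missing_max Remove samples with missingness above this.
#' @param kinship_max Remove one member of pairs with PI_HAT at or above
#'   this (`NA` disables).
#' @param ld_prune_r2 Prune markers so no within-window pair has r2 at or
#'   above this (`NA` disables).
#' @param drop_sex_unmapped Drop sex-chromosome, unmapped and linkage-group
#'   markers.
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0, hwe_p_min = NA, marker_missing_max = 1,
                      sample_missing_max = 1, kinship_max = NA,
                      ld_prune_r2 = NA, drop_sex_unmapped = TRUE) {
  fr <- c(maf_min = maf_min, marker_missing_max = marker_missing_max,
          sample_missing_max = sample_missing_max)
  if (any(fr < 0 | fr > 1)) abort("config error: fractions must lie in [0, 1]")
  if (!is.na(hwe_p_min) && (hwe_p_min < 0 || hwe_p_min > 1)) {
    abort("config error: hwe_p_min must lie in [0, 1]")
  }
  if (!is.na(kinship_max) && (kinship_max < 0 || kinship_max > 1)) {
    abort("config error: kinship_max must lie in [0, 1]")
  }
  if (!is.na(ld_prune_r2) && (ld_prune_r2 < 0 || ld_prune_r2 > 1)) {
    abort("config error: ld_prune_r2 must lie in [0, 1]")
  }
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 marker_missing_max = marker_missing_max,
                 sample_missing_max = sample_missing_max,
                 kinship_max = kinship_max, ld_prune_r2 = ld_prune_r2,
                 drop_sex_unmapped = isTRUE(drop_sex_unmapped)),
            class = "qc_config")
}

#' @rdname qc_config
#' @param preset `"structure"` or `"ld"`.
#' @export
qc_preset <- function(preset = c("structure", "ld")) {
  switch(match.arg(preset),
    structure = qc_config(maf_min = 0.02, hwe_p_min = NA,
                          marker_missing_max = 0.05,
                          sample_missing_max = 0.05,
                          kinship_max = 0.45, ld_prune_r2 = 0.2),
    ld = qc_config(maf_min = 0.05, hwe_p_min = 0.001,
                   marker_missing_max = 0.05, sample_missing_max = 0.05,
                   kinship_max = 0.45, ld_prune_r2 = NA))
}

#' Staged marker filtering
#'
#' Applies the marker filters in a fixed order: sex-chromosome/unmapped
#' markers, marker missingness, monomorphic markers, MAF, HWE.  MAF and HWE
#' are computed on the non-missing calls of the cohort's current sample set,
#' so drop high-missingness samples (see [qc_cohort()]) before calling this
#' if that is intended.
#'
#' @param x A [geno_cohort()].
#' @param config A [qc_config()].
#' @return List with elements `cohort` (filtered), `report` (attrition
#'   tibble: `stage`, `domain`, `removed`, `retained`) and `removed` (named
#'   list of removed marker ids per stage).
#' @export
filter_markers <- function(x, config = qc_preset("ld")) {
  stopifnot(inherits(config, "qc_config"))
  removed <- list()
  report <- list()
  note <- function(stage, ids) {
    removed[[stage]] <<- ids
    report[[stage]] <<- tibble::tibble(
      stage = stage, domain = "marker",
      removed = length(ids), retained = n_markers(x))
  }

  if (config$drop_sex_unmapped) {
    cls <- chrom_class(x$markers$chrom)
    sex <- x$markers$marker_id[cls == "sex"]
    x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, sex))
    note("sex_chromosome", sex)
    cls <- chrom_class(x$markers$chrom)
    unm <- x$markers$marker_id[cls %in% c("unmapped", "linkage_group")]
    x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, unm))
    note("unmapped", unm)
  } else {
    note("sex_chromosome", character(0))
    note("unmapped", character(0))
  }

  mr <- marker_missing_rate(x)
  ids <- mr$marker_id[mr$missing_rate > config$marker_missing_max]
  x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, ids))
  note("marker_missing", ids)

  fr <- allele_freq(x)
  ids <- fr$marker_id[is.na(fr$maf) | fr$maf == 0]
  x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, ids))
  note("monomorphic", ids)

  fr <- allele_freq(x)
  ids <- fr$marker_id[fr$maf <= config$maf_min]
  x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, ids))
  note("maf", ids)

  if (!is.na(config$hwe_p_min)) {
    g <- x$calls
    p <- hwe_exact_p(colSums(g == 0L, na.rm = TRUE),
                     colSums(g == 1L, na.rm = TRUE),
                     colSums(g == 2L, na.rm = TRUE))
    ids <- x$markers$marker_id[p <= config$hwe_p_min]
    x <- cohort_subset(x, marker_ids = setdiff(x$markers$marker_id, ids))
  } else {
    ids <- character(0)
  }
  note("hwe", ids)

  if (n_markers(x) == 0) warn("all markers removed by QC")
  list(cohort = x, report = dplyr::bind_rows(report), removed = removed)
}

#' LD pruning by sliding-window greedy removal
#'
#' Within each sliding window of `window_markers` markers (advancing by
#' `step`), the highest-r2 pair at or above `r2_threshold` is found and its
#' member with the lower MAF dropped (ties: the later map position), until no
#' within-window pair reaches the threshold.  The surviving marker set has no
#' within-window pair with r2 at or above the threshold.
#'
#' @param x A [geno_cohort()].
#' @param r2_threshold Pruning threshold, default 0.2.
#' @param window_markers Window size in markers, default 50.
#' @param step Window step in markers, default 5.
#' @return Character vector of retained marker ids, with the removed ids as
#'   attribute `"removed"`.
#' @export
prune_ld <- function(x, r2_threshold = 0.2, window_markers = 50L, step = 5L) {
  if (window_markers < 2) abort("config error: window_markers must be >= 2")
  fr <- allele_freq(x)
  maf <- stats::setNames(fr$maf, fr$marker_id)
  dropped <- character(0)
  for (chr in unique(x$markers$chrom)) {
    mk <- x$markers[x$markers$chrom == chr, ]
    g <- x$calls[, x$markers$chrom == chr, drop = FALSE]
    L <- nrow(mk)
    if (L < 2) next
    alive <- rep(TRUE, L)
    starts <- seq(1L, max(1L, L - 1L), by = step)
    for (s in starts) {
      win <- s:min(L, s + window_markers - 1L)
      win <- win[alive[win]]
      if (length(win) < 2) next
      pr <- t(utils::combn(win, 2L))
      r2 <- r2_pairs_genotypes(g, pr[, 1], pr[, 2])$r2
      while (length(r2) && max(r2) >= r2_threshold) {
        w <- which.max(r2)
        cand <- c(pr[w, 1], pr[w, 2])
        m <- maf[mk$marker_id[cand]]
        drop <- if (m[1] != m[2]) cand[which.min(m)] else max(cand)
        alive[drop] <- FALSE
        dropped <- c(dropped, mk$marker_id[drop])
        keep <- pr[, 1] != drop & pr[, 2] != drop
        pr <- pr[keep, , drop = FALSE]
        r2 <- r2[keep]
      }
    }
  }
  retained <- setdiff(x$markers$marker_id, dropped)
  attr(retained, "removed") <- dropped
  retained
}

#' Full staged QC pipeline
#'
#' Application order: sample missingness, then the marker stages of
#' [filter_markers()] (sex/unmapped, marker missingness, monomorphic, MAF,
#' HWE), then kinship-based sample removal ([kinship_ibd()] +
#' [drop_related()]), then optional LD pruning ([prune_ld()]).  The report
#' lists one row per stage in true application order; removed plus retained
#' equals the input total within each domain.
#'
#' @param x A [geno_cohort()].
#' @param config A [qc_config()] or preset name (`"structure"`/`"ld"`).
#' @return List of class `popld_qc`: `cohort`, `report`, `removed` (named
#'   list of removed ids per stage), `kinship` (pair table or `NULL`).
#' @export
qc_cohort <- function(x, config = "ld") {
  if (is.character(config)) config <- qc_preset(config)
  stopifnot(inherits(config, "qc_config"))
  removed <- list()

  sm <- sample_missing_rate(x)
  ids <- sm$sample_id[sm$missing_rate > config$sample_missing_max]
  x <- cohort_subset(x, sample_ids = setdiff(x$samples$sample_id, ids))
  removed$sample_missing <- ids
  rep_sm <- tibble::tibble(stage = "sample_missing", domain = "sample",
                           removed = length(ids), retained = n_samples(x))

  fm <- filter_markers(x, config)
  x <- fm$cohort
  removed <- c(removed, fm$removed)

  kin <- NULL
  if (!is.na(config$kinship_max) && n_samples(x) >= 2 && n_markers(x) >= 1) {
    kin <- kinship_ibd(x)
    x2 <- drop_related(x, kin, config$kinship_max)
    removed$kinship <- attr(x2, "removed") %||% character(0)
    x <- x2
  } else {
    removed$kinship <- character(0)
  }
  rep_kin <- tibble::tibble(stage = "kinship", domain = "sample",
                            removed = length(removed$kinship),
                            retained = n_samples(x))

  if (!is.na(config$ld_prune_r2) && n_markers(x) >= 2) {
    keep <- prune_ld(x, r2_threshold = config$ld_prune_r2)
    removed$ld_pruned <- attr(keep, "removed")
    x <- cohort_subset(x, marker_ids = keep)
  } else {
    removed$ld_pruned <- character(0)
  }
  rep_prune <- tibble::tibble(stage = "ld_pruned", domain = "marker",
                              removed = length(removed$ld_pruned),
                              retained = n_markers(x))

  report <- dplyr::bind_rows(rep_sm, fm$report, rep_kin, rep_prune)
  structure(list(cohort = x, report = report, removed = removed,
                 kinship = kin),
            class = "popld_qc")
}

#' @export
print.popld_qc <- function(x, ...) {
  cat("<popld_qc>\n")
  print(x$report)
  invisible(x)
}

#' Write a QC attrition report as TSV
#'
#' @param qc A `popld_qc` object (or its `report` tibble).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(qc, path) {
  rep <- if (inherits(qc, "popld_qc")) qc$report else qc
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
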