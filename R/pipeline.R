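#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end survey on one cohort: structure-regime QC
#' followed by PCA on the pooled cohort; LD-regime QC per population followed
#' by diversity statistics, the windowed r-squared scan, distance-binned
#' decay curves, the cross-population fixed-effects LD model (when two or
#' more populations and chromosomes are present) and the Ne trajectory.
#' Each stage's table is written as TSV into `out_dir` together with a
#' manifest (package version, config hash, seed), and the full set of result
#' tibbles is returned invisibly.  Stage failures halt with an error naming
#' the stage; tables already written are retained.
#'
#' @param x A [geno_cohort()].
#' @param rmap A [recomb_map()] for the Ne stage (`NULL` skips Ne).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param bin_edges_kb Decay/Ne bin edges (kb).
#' @param macro_chroms Chromosome labels given the extended macro-chromosome
#'   binning (up to 10000 kb); default `c("1","2","3","4","5")`.
#' @param alpha Mutation parameter for Ne (1 or 2).
#' @param window_snps,window_kb LD scan windows.
#' @param seed Seed recorded in the manifest and set before running (the
#'   pipeline itself is deterministic; the seed guards any future stochastic
#'   stage).
#' @return Invisibly, a named list of result tibbles: `qc_structure`,
#'   `pca`, `qc_ld` (per population), `diversity`, `maf_spectrum`, `ld`,
#'   `decay`, `decay_macro`, `ld_anova`, `ne`.
#' @export
run_pipeline <- function(x, rmap = NULL, out_dir = NULL,
                         bin_edges_kb = c(10, 20, 40, 60, 100, 200, 500,
                                          1000, 2000, 5000),
                         macro_chroms = as.character(1:5),
                         alpha = 1, window_snps = 5000L, window_kb = 10000,
                         seed = 1L) {
  set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      utils::write.table(tbl, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tbl
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }
  res <- list()

  qc_s <- stage("qc_structure", qc_cohort(x, "structure"))
  res$qc_structure <- emit(qc_s$report, "qc_structure")
  res$pca <- stage("pca", emit(pca_genotypes(qc_s$cohort,
                                             k = min(10L, n_samples(qc_s$cohort) - 1L)),
                               "pca"))

  pops <- unique(x$samples$population)
  per_pop <- lapply(pops, function(p) {
    sub <- cohort_subset(x, sample_ids =
                           x$samples$sample_id[x$samples$population == p])
    qc <- stage(paste0("qc_ld:", p), qc_cohort(sub, "ld"))
    qc
  })
  names(per_pop) <- pops
  res$qc_ld <- emit(dplyr::bind_rows(lapply(pops, function(p)
    dplyr::mutate(per_pop[[p]]$report, population = p, .before = 1))),
    "qc_ld")

  res$diversity <- stage("diversity", emit(dplyr::bind_rows(
    lapply(per_pop, function(qc) diversity_summary(qc$cohort))), "diversity"))
  res$maf_spectrum <- stage("maf_spectrum", emit(dplyr::bind_rows(
    lapply(pops, function(p)
      maf_spectrum(per_pop[[p]]$cohort) |>
        dplyr::mutate(population = p, .before = 1))), "maf_spectrum"))

  res$ld <- stage("ld", emit(dplyr::bind_rows(lapply(per_pop, function(qc)
    ld_scan(qc$cohort, window_snps = window_snps, window_kb = window_kb))),
    "ld"))
  res$decay <- stage("decay", emit(decay_curve(res$ld, bin_edges_kb), "decay"))
  macro <- res$ld[res$ld$chrom %in% macro_chroms, ]
  res$decay_macro <- if (nrow(macro)) {
    stage("decay_macro", emit(decay_curve(macro, c(bin_edges_kb, 10000)),
                              "decay_macro"))
  } else NULL

  res$ld_anova <- if (length(pops) >= 2 && length(unique(res$ld$chrom)) >= 2) {
    fit <- stage("ld_anova", ld_anova(res$ld))
    emit(tidy(fit), "ld_anova")
    fit
  } else NULL

  if (!is.null(rmap)) {
    res$ne <- stage("ne", emit(dplyr::bind_rows(lapply(pops, function(p) {
      recs <- res$ld[res$ld$population == p, ]
      n_chr <- 2L * sum(per_pop[[p]]$cohort$samples$population == p)
      ne_trajectory(recs, rmap, n_chr, bin_edges_kb, alpha = alpha)
    })), "ne"))
  } else if (!is.null(out_dir)) {
    inform("no recombination map supplied: Ne stage skipped")
  }

  if (!is.null(out_dir)) {
    manifest <- list(
      package = "popld",
      version = as.character(utils::packageVersion("popld")),
      seed = seed,
      config_hash = rlang::hash(list(bin_edges_kb, macro_chroms, alpha,
                                     window_snps, window_kb)),
      n_samples = n_samples(x), n_markers = n_markers(x),
      populations = pops)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  invisible(res)
}
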