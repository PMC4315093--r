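#' Simulation configuration
#'
#' Study-condition settings for the forward Wright-Fisher simulator.
#' Epochs are ordered past to present; the population is burned in for
#' `burn_in` generations (default four times the first epoch's Ne) at the
#' first epoch's size before the epoch schedule runs, so that founder LD has
#' equilibrated under drift and recombination.
#'
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @param epochs Data frame with columns `duration` (generations) and `ne`
#'   (diploid size), past to present.
#' @param chromosomes Data frame with columns `chrom`, `bp_length`,
#'   `morgans`.
#' @param n_markers Founder marker panel size per chromosome (segregating
#'   sites are a subset after drift and ascertainment).
#' @param n_sample Diploid individuals sampled per population.
#' @param n_populations Number of terminal populations (default 1).
#' @param split_generations Generations each terminal population evolves
#'   independently after the split (required if `n_populations > 1`).
#' @param missing_rate Fraction of calls set missing at random (default 0).
#' @param maf_floor Ascertainment floor: emitted markers must reach this MAF
#'   in the pooled sample (default 0.05).
#' @param burn_in Burn-in generations (default `4 * epochs$ne[1]`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       epochs = data.frame(duration = 100, ne = 100),
                       chromosomes = data.frame(chrom = "1",
                                                bp_length = 5e7,
                                                morgans = 0.5),
                       n_markers = 500L, n_sample = 25L,
                       n_populations = 1L, split_generations = 0L,
                       missing_rate = 0, maf_floor = 0.05,
                       burn_in = NULL) {
  if (missing(seed)) abort("config error: seed is mandatory")
  epochs <- tibble::as_tibble(epochs)
  chromosomes <- tibble::as_tibble(chromosomes)
  chromosomes$chrom <- as.character(chromosomes$chrom)
  stopifnot(all(epochs$duration >= 0), all(epochs$ne >= 1),
            all(chromosomes$bp_length > 0), all(chromosomes$morgans >= 0),
            n_markers >= 1, n_sample >= 1, n_populations >= 1,
            missing_rate >= 0, missing_rate < 1,
            maf_floor >= 0, maf_floor < 0.5)
  if (any(n_markers > chromosomes$bp_length - 1)) {
    abort("config error: n_markers exceeds feasible sites on a chromosome")
  }
  if (n_populations > 1 && split_generations < 1) {
    abort("config error: split_generations required when n_populations > 1")
  }
  if (is.null(burn_in)) burn_in <- 4L * epochs$ne[1]
  structure(list(seed = as.integer(seed), epochs = epochs,
                 chromosomes = chromosomes, n_markers = as.integer(n_markers),
                 n_sample = as.integer(n_sample),
                 n_populations = as.integer(n_populations),
                 split_generations = as.integer(split_generations),
                 missing_rate = missing_rate, maf_floor = maf_floor,
                 burn_in = as.integer(burn_in)),
            class = "sim_config")
}

#' Forward Wright-Fisher simulation of a genotyped cohort
#'
#' Discrete-generation Wright-Fisher with recombination: founder haplotypes
#' carry allele frequencies drawn from a symmetric Beta(0.5, 0.5) spectrum;
#' each generation, every offspring draws two parents uniformly and receives
#' one recombinant gamete from each (crossover count Poisson with mean equal
#' to the chromosome's genetic length, breakpoints uniform in genetic
#' distance).  After burn-in and the epoch schedule, optional population
#' splits evolve independently at the final epoch's Ne.  Sampled diploid
#' genotypes are emitted unphased; the phased truth, the demographic truth
#' and any planted violations live in the returned truth ledger.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `cohort` (a [geno_cohort()]) and `ledger`
#'   (truth ledger: epochs, per-marker founder frequencies, phased
#'   haplotypes of the sampled individuals, planted-violation and
#'   relative-pair tables).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ne_seq <- c(rep(config$epochs$ne[1], config$burn_in),
              rep(config$epochs$ne, config$epochs$duration))
  ne_final <- config$epochs$ne[nrow(config$epochs)]

  per_chrom <- lapply(seq_len(nrow(config$chromosomes)), function(ci) {
    chrom <- config$chromosomes$chrom[ci]
    bp_len <- config$chromosomes$bp_length[ci]
    morgans <- config$chromosomes$morgans[ci]
    L <- config$n_markers
    p0 <- stats::rbeta(L, 0.5, 0.5)
    pos <- sort(sample.int(bp_len - 1L, L))
    gpos <- pos / bp_len * morgans
    n0 <- config$epochs$ne[1]
    founders <- matrix(stats::rbinom(2L * n0 * L, 1L, rep(p0, each = 2L * n0)),
                       nrow = 2L * n0)
    H <- wf_evolve_cpp(founders, gpos, morgans, as.integer(ne_seq))
    pops <- lapply(seq_len(config$n_populations), function(p) {
      Hp <- if (config$n_populations > 1) {
        wf_evolve_cpp(H, gpos, morgans,
                      as.integer(rep(ne_final, config$split_generations)))
      } else H
      Hp[seq_len(2L * config$n_sample), , drop = FALSE]
    })
    list(chrom = chrom, pos = pos, p0 = p0, pops = pops)
  })

  n_pop <- config$n_populations
  n_s <- config$n_sample
  haps <- lapply(seq_len(n_pop), function(p)
    do.call(cbind, lapply(per_chrom, function(pc) pc$pops[[p]])))
  markers <- dplyr::bind_rows(lapply(per_chrom, function(pc)
    tibble::tibble(chrom = pc$chrom, pos_bp = pc$pos, founder_freq = pc$p0)))
  markers$marker_id <- sprintf("c%s_m%06d", markers$chrom, markers$pos_bp)

  odd <- seq(1L, 2L * n_s, by = 2L)
  geno <- do.call(rbind, lapply(haps, function(H) H[odd, ] + H[odd + 1L, ]))
  samples <- tibble::tibble(
    sample_id = as.vector(vapply(seq_len(n_pop), function(p)
      sprintf("pop%d_i%03d", p, seq_len(n_s)), character(n_s))),
    population = rep(sprintf("pop%d", seq_len(n_pop)), each = n_s))

  # ascertainment on the pooled sample
  p_hat <- colMeans(geno) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  keep <- maf >= config$maf_floor
  geno <- geno[, keep, drop = FALSE]
  markers <- markers[keep, ]
  phased <- lapply(haps, function(H) {
    H <- H[, keep, drop = FALSE]
    colnames(H) <- markers$marker_id
    H
  })
  names(phased) <- sprintf("pop%d", seq_len(n_pop))

  calls <- geno
  storage.mode(calls) <- "integer"
  if (config$missing_rate > 0) {
    n_miss <- round(config$missing_rate * length(calls))
    calls[sample.int(length(calls), n_miss)] <- NA_integer_
  }

  cohort <- geno_cohort(
    calls,
    tibble::tibble(marker_id = markers$marker_id, chrom = markers$chrom,
                   pos_bp = markers$pos_bp, allele_a = "A", allele_b = "G"),
    samples)

  # generation-time consistency check: unphased calls match phased truth
  for (p in seq_len(n_pop)) {
    g_true <- phased[[p]][odd, , drop = FALSE] + phased[[p]][odd + 1L, , drop = FALSE]
    g_emit <- geno[samples$population == sprintf("pop%d", p), , drop = FALSE]
    stopifnot(identical(unname(g_true), unname(g_emit)))
  }

  ledger <- list(seed = config$seed, epochs = config$epochs,
                 chromosomes = config$chromosomes, burn_in = config$burn_in,
                 n_founder_markers = config$n_markers *
                   nrow(config$chromosomes),
                 n_emitted_markers = nrow(markers),
                 maf_floor = config$maf_floor,
                 missing_rate = config$missing_rate,
                 founder_freq = markers$founder_freq,
                 phased = phased,
                 planted = tibble::tibble(kind = character(),
                                          id = character()),
                 relatives = tibble::tibble(sample_1 = character(),
                                            sample_2 = character(),
                                            relation = character()))
  list(cohort = cohort, ledger = ledger)
}

#' Plant QC violations into a simulated cohort
#'
#' Appends samples and markers that the staged QC filters must catch:
#' duplicated samples, parent-offspring duos, high-missingness samples,
#' monomorphic markers, markers pushed below a MAF floor, heterozygote-excess
#' (HWE-violating) markers and high-missingness markers.  Every planted
#' record is written to the ledger so QC behaviour can be cross-checked
#' exactly.  Planting happens after ascertainment, so the ascertainment
#' floor never removes planted markers.
#'
#' @param sim A list `(cohort, ledger)` from [simulate_cohort()].
#' @param spec Named list of counts: `n_duplicate`, `n_parent_offspring`,
#'   `n_high_missing_sample`, `n_monomorphic`, `n_low_maf`, `n_hwe`,
#'   `n_high_missing_marker` (all default 0).  Optional `low_maf_target`
#'   (default 0.02) and `missing_target` (default 0.2).
#' @return A list `(cohort, ledger)` with the violations planted.
#' @export
plant_violations <- function(sim, spec = list()) {
  defaults <- list(n_duplicate = 0L, n_parent_offspring = 0L,
                   n_high_missing_sample = 0L, n_monomorphic = 0L,
                   n_low_maf = 0L, n_hwe = 0L, n_high_missing_marker = 0L,
                   low_maf_target = 0.02, missing_target = 0.2)
  unknown <- setdiff(names(spec), names(defaults))
  if (length(unknown)) abort(paste("config error: unknown spec field(s):",
                                   paste(unknown, collapse = ", ")))
  sp <- utils::modifyList(defaults, spec)
  counts <- unlist(sp[startsWith(names(sp), "n_")])
  if (all(counts == 0)) return(sim)

  cohort <- sim$cohort
  ledger <- sim$ledger
  calls <- cohort$calls
  markers <- cohort$markers
  samples <- cohort$samples
  if ((sp$n_duplicate + sp$n_parent_offspring) > 0 && nrow(samples) < 1) {
    abort("config error: no source samples to duplicate")
  }
  fr <- colSums(calls, na.rm = TRUE) / (2 * pmax(colSums(!is.na(calls)), 1))

  planted <- ledger$planted
  relatives <- ledger$relatives

  add_sample <- function(calls, samples, new_calls, id, population) {
    calls <- rbind(calls, new_calls)
    samples <- dplyr::bind_rows(samples,
      tibble::tibble(sample_id = id, population = population))
    list(calls = calls, samples = samples)
  }

  for (k in seq_len(sp$n_duplicate)) {
    src <- sample(nrow(samples), 1)
    id <- sprintf("dup_%02d", k)
    res <- add_sample(calls, samples, calls[src, ], id,
                      samples$population[src])
    calls <- res$calls; samples <- res$samples
    relatives <- dplyr::bind_rows(relatives,
      tibble::tibble(sample_1 = samples$sample_id[src], sample_2 = id,
                     relation = "duplicate"))
    planted <- dplyr::bind_rows(planted,
      tibble::tibble(kind = "kinship", id = id))
  }

  for (k in seq_len(sp$n_parent_offspring)) {
    src <- sample(which(!startsWith(samples$sample_id, "dup_")), 1)
    g_par <- calls[src, ]
    a1 <- ifelse(is.na(g_par), stats::rbinom(length(g_par), 1L, fr),
          ifelse(g_par == 0L, 0L,
          ifelse(g_par == 2L, 1L, stats::rbinom(length(g_par), 1L, 0.5))))
    a2 <- stats::rbinom(length(g_par), 1L, fr)
    id <- sprintf("po_%02d", k)
    res <- add_sample(calls, samples, as.integer(a1 + a2), id,
                      samples$population[src])
    calls <- res$calls; samples <- res$samples
    relatives <- dplyr::bind_rows(relatives,
      tibble::tibble(sample_1 = samples$sample_id[src], sample_2 = id,
                     relation = "parent_offspring"))
    planted <- dplyr::bind_rows(planted,
      tibble::tibble(kind = "kinship", id = id))
  }

  for (k in seq_len(sp$n_high_missing_sample)) {
    g <- stats::rbinom(ncol(calls), 2L, fr)
    g[sample.int(length(g), round(sp$missing_target * length(g)))] <- NA_integer_
    id <- sprintf("hms_%02d", k)
    res <- add_sample(calls, samples, as.integer(g), id,
                      samples$population[1])
    calls <- res$calls; samples <- res$samples
    planted <- dplyr::bind_rows(planted,
      tibble::tibble(kind = "sample_missing", id = id))
  }

  n <- nrow(samples)
  used_pos <- split(markers$pos_bp, markers$chrom)
  chrom_len <- if (!is.null(ledger$chromosomes)) {
    stats::setNames(ledger$chromosomes$bp_length, ledger$chromosomes$chrom)
  } else {
    vapply(split(markers$pos_bp, markers$chrom), function(p)
      max(p) + 1e6, numeric(1))
  }
  new_pos <- function() {
    chr <- sample(names(used_pos), 1)
    repeat {
      pos <- sample.int(chrom_len[[chr]] - 1L, 1)
      if (!pos %in% used_pos[[chr]]) break
    }
    used_pos[[chr]] <<- c(used_pos[[chr]], pos)
    list(chrom = chr, pos = pos)
  }
  add_marker <- function(calls, markers, g, id, kind) {
    loc <- new_pos()
    calls <- cbind(calls, as.integer(g))
    markers <- dplyr::bind_rows(markers,
      tibble::tibble(marker_id = id, chrom = loc$chrom,
                     pos_bp = as.integer(loc$pos),
                     allele_a = "A", allele_b = "G"))
    planted <<- dplyr::bind_rows(planted, tibble::tibble(kind = kind, id = id))
    list(calls = calls, markers = markers)
  }

  for (k in seq_len(sp$n_monomorphic)) {
    res <- add_marker(calls, markers, rep(0L, n),
                      sprintf("mono_%03d", k), "monomorphic")
    calls <- res$calls; markers <- res$markers
  }
  # low-MAF carriers must survive the sample filters, or the marker would
  # degrade to monomorphic before its MAF stage
  stable <- which(!samples$sample_id %in%
                    planted$id[planted$kind == "sample_missing"])
  for (k in seq_len(sp$n_low_maf)) {
    n_car <- max(1L, round(sp$low_maf_target * 2 * n))
    g <- rep(0L, n)
    g[sample(stable, min(length(stable), n_car))] <- 1L
    res <- add_marker(calls, markers, g, sprintf("lowmaf_%03d", k), "maf")
    calls <- res$calls; markers <- res$markers
  }
  for (k in seq_len(sp$n_hwe)) {
    res <- add_marker(calls, markers, rep(1L, n),
                      sprintf("hwe_%03d", k), "hwe")
    calls <- res$calls; markers <- res$markers
  }
  for (k in seq_len(sp$n_high_missing_marker)) {
    g <- stats::rbinom(n, 2L, 0.3)
    g[sample.int(n, round(sp$missing_target * n))] <- NA_integer_
    res <- add_marker(calls, markers, g,
                      sprintf("hmm_%03d", k), "marker_missing")
    calls <- res$calls; markers <- res$markers
  }

  ledger$planted <- planted
  ledger$relatives <- relatives
  list(cohort = geno_cohort(calls, markers, samples), ledger = ledger)
}

#' Serialise a truth ledger to JSON
#'
#' Writes the machine-readable part of the ledger (demography, planted
#' violations, relative pairs, counts); phased haplotypes are omitted.
#'
#' @param ledger Ledger from [simulate_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_ledger <- function(ledger, path) {
  out <- ledger[setdiff(names(ledger), c("phased", "founder_freq"))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
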