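#' Read a whitespace-delimited PED/MAP genotype cohort
#'
#' The PED dialect has six leading columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per marker; the
#' family column is used as the population label.  The MAP dialect has four
#' columns (chromosome, marker id, genetic position, bp position) or six
#' columns with two trailing allele columns (`allele_a`, `allele_b`); when
#' the allele columns are present, `allele_b` is the counted allele.  With a
#' four-column map, `allele_b` is taken as the lexicographically larger
#' allele observed at the marker, which is stable but arbitrary (all
#' downstream statistics are orientation-invariant).
#'
#' `"0 0"` allele pairs are read as missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [geno_cohort()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_tok)) {
    len <- lengths(map_tok)
    if (!all(len %in% c(4L, 6L)) || length(unique(len)) > 1) {
      bad <- which(!len %in% c(4L, 6L))[1] %||% 1L
      abort(sprintf("parse error in %s: line %d has %d fields (expected 4 or 6)",
                    map_path, bad, len[bad]))
    }
  }
  has_alleles <- length(map_tok) > 0 && lengths(map_tok)[1] == 6L
  markers <- tibble::tibble(
    chrom = vapply(map_tok, `[`, "", 1),
    marker_id = vapply(map_tok, `[`, "", 2),
    pos_cm = as.numeric(vapply(map_tok, `[`, "", 3)),
    pos_bp = as.integer(vapply(map_tok, `[`, "", 4))
  )
  if (has_alleles) {
    markers$allele_a <- vapply(map_tok, `[`, "", 5)
    markers$allele_b <- vapply(map_tok, `[`, "", 6)
  }
  m <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  fam <- iid <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      if ((length(tok) - 6) %% 2 == 0 && length(tok) > 6) {
        abort(sprintf(
          "dimension error in %s: line %d carries %d markers but map has %d",
          ped_path, i, (length(tok) - 6) %/% 2, m))
      }
      abort(sprintf("parse error in %s: line %d has %d fields (expected %d)",
                    ped_path, i, length(tok), 6 + 2 * m))
    }
    fam[i] <- tok[1]
    iid[i] <- tok[2]
    if (m > 0) {
      g <- tok[-(1:6)]
      a1[i, ] <- g[seq(1, 2 * m, by = 2)]
      a2[i, ] <- g[seq(2, 2 * m, by = 2)]
    }
  }
  valid <- c("A", "C", "G", "T", "0")
  bad <- matrix(!(a1 %in% valid) | !(a2 %in% valid), nrow = n)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("format error in %s: allele symbol %s at line %d, marker %s",
                  ped_path, a1[idx[1], idx[2]], idx[1],
                  markers$marker_id[idx[2]]))
  }

  if (!has_alleles) {
    markers$allele_a <- NA_character_
    markers$allele_b <- NA_character_
    for (j in seq_len(m)) {
      obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
      markers$allele_a[j] <- if (length(obs) >= 1) obs[1] else "0"
      markers$allele_b[j] <- if (length(obs) >= 2) obs[2] else "0"
    }
  }

  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] == markers$allele_b[j]) +
                  (a2[, j] == markers$allele_b[j])
    calls[miss, j] <- NA_integer_
  }

  samples <- tibble::tibble(sample_id = iid, population = fam)
  geno_cohort(calls, markers[, c("marker_id", "chrom", "pos_bp",
                                 "allele_a", "allele_b")], samples)
}

#' Write a cohort as PED/MAP text files
#'
#' Missing calls are written as `"0 0"`.  By default the map is written with
#' six columns (including the two allele labels) so that
#' [read_ped_map()] round-trips the call matrix exactly; set
#' `map_alleles = FALSE` for the plain four-column dialect.
#'
#' @param x A [geno_cohort()].
#' @param ped_path,map_path Output paths.
#' @param map_alleles Write allele columns into the map (default `TRUE`).
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(x, ped_path, map_path, map_alleles = TRUE) {
  mk <- x$markers
  map_cols <- list(mk$chrom, mk$marker_id, rep(0, nrow(mk)), mk$pos_bp)
  if (map_alleles) map_cols <- c(map_cols, list(mk$allele_a, mk$allele_b))
  writeLines(do.call(paste, c(map_cols, sep = "\t")), map_path)

  n <- n_samples(x); m <- n_markers(x)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- x$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, mk$allele_b, mk$allele_a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, mk$allele_b, mk$allele_a))
    geno <- character(2 * m)
    if (m > 0) {
      geno[seq(1, 2 * m, 2)] <- a1
      geno[seq(2, 2 * m, 2)] <- a2
    }
    lines[i] <- paste(c(x$samples$population[i], x$samples$sample_id[i],
                        "0", "0", "0", "-9", geno), collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a two-column population assignment table
#'
#' @param path TSV with columns `sample_id`, `population` (header optional
#'   but recommended).
#' @return Tibble with `sample_id`, `population`.
#' @export
read_pop_table <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", first, ignore.case = TRUE)
  df <- if (header) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = FALSE, sep = "\t",
                      col.names = c("sample_id", "population"),
                      stringsAsFactors = FALSE)
  }
  names(df)[1:2] <- c("sample_id", "population")
  tibble::as_tibble(df[, 1:2])
}

#' Read a per-chromosome recombination (genetic length) table
#'
#' @param path TSV with header columns `chrom`, `bp_length`, `morgans`.
#' @return A recombination map tibble with the per-bp rate
#'   `morgans_per_bp = morgans / bp_length` appended; see [recomb_map()].
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  recomb_map(df$chrom, df$bp_length, df$morgans)
}

#' Construct a recombination map
#'
#' Holds, per chromosome, the physical length in bp, the genetic length in
#' Morgans, and their ratio (the mean recombination rate in Morgans per bp)
#' used to convert physical marker intervals to genetic distances.
#'
#' @param chrom Chromosome labels.
#' @param bp_length Physical lengths (bp).
#' @param morgans Genetic lengths (Morgans).
#' @return Tibble with columns `chrom`, `bp_length`, `morgans`,
#'   `morgans_per_bp`.
#' @export
recomb_map <- function(chrom, bp_length, morgans) {
  stopifnot(length(chrom) == length(bp_length),
            length(chrom) == length(morgans))
  if (any(bp_length <= 0) || any(morgans <= 0)) {
    abort("bp_length and morgans must be positive")
  }
  tibble::tibble(chrom = as.character(chrom),
                 bp_length = as.numeric(bp_length),
                 morgans = as.numeric(morgans),
                 morgans_per_bp = morgans / bp_length)
}

#' Read a VCF file into a genotype cohort (optional adapter)
#'
#' Thin adapter over the `vcfR` package mapping biallelic SNP records onto
#' the same container as [read_ped_map()]; `allele_b` is the ALT allele.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param populations Optional tibble (`sample_id`, `population`); samples
#'   absent from it are labelled `"unassigned"`.
#' @return A [geno_cohort()].
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf() needs the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  alt_count <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           (substr(x, 1, 1) == "1") + (substr(x, 3, 3) == "1"))
  }
  calls <- t(apply(gt, 1, alt_count))
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[keep, "CHROM"], ":",
                                         fix[keep, "POS"])[is.na(ids) | ids == "."]
  markers <- tibble::tibble(marker_id = ids,
                            chrom = fix[keep, "CHROM"],
                            pos_bp = as.integer(fix[keep, "POS"]),
                            allele_a = fix[keep, "REF"],
                            allele_b = fix[keep, "ALT"])
  sample_ids <- colnames(gt)
  pop <- rep("unassigned", length(sample_ids))
  if (!is.null(populations)) {
    m <- match(sample_ids, populations$sample_id)
    pop[!is.na(m)] <- populations$population[m[!is.na(m)]]
  }
  geno_cohort(t(calls) * 1L, markers,
              tibble::tibble(sample_id = sample_ids, population = pop))
}

#' Default chicken recombination table (synthetic approximation)
#'
#' Returns the packaged per-chromosome genetic-length table for the 28
#' chicken autosomes.  The values are a constructed, literature-style
#' approximation (macro-chromosomes near 2 cM/Mb rising to >10 cM/Mb on the
#' smallest micro-chromosomes), shipped so that real-data runs have a
#' sensible default; they are not measured map lengths.  Validation runs use
#' simulator-defined maps instead.
#'
#' @return A [recomb_map()] tibble.
#' @export
chicken_recomb_map <- function() {
  read_recomb_map(system.file("extdata", "chicken_recomb_map_synthetic.tsv",
                              package = "popld", mustWork = TRUE))
}
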