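Package: popld
Title: SNP Quality Control, Linkage Disequilibrium Decay and LD-Based
    Effective Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for population-genomic surveys of
    diploid SNP-array cohorts, built around the analysis stages used for
    village and conservation poultry flocks: staged marker and sample
    quality control (missingness, monomorphism, minor allele frequency,
    Hardy-Weinberg exact test, method-of-moments kinship, LD pruning),
    per-population diversity statistics (observed and expected
    heterozygosity, inbreeding coefficients, allele-frequency spectra,
    principal components), within-chromosome pairwise r-squared with
    windowed scans and distance-binned decay curves, a crossed
    fixed-effects model for LD, and effective-population-size
    trajectories from the Sved/Corbin relation E[r2_adj] = 1/(alpha +
    4*Ne*c).  A forward-in-time Wright-Fisher simulator with
    recombination, piecewise-constant Ne, planted QC violations and a
    machine-readable truth ledger provides end-to-end validation with
    known demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
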