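#' Fixed-effects model for pairwise LD
#'
#' Fits the crossed fixed-effects model
#' \deqn{r^2 = \mu + Pop + Chr + (Pop \times Chr) + b\,dist + e}
#' by ordinary least squares, with population and chromosome as factors,
#' their interaction, and the physical marker separation (bp) as a covariate.
#' Terms are tested with Type-I (sequential) F-tests in the stated order.
#'
#' Rank deficiency from empty population-by-chromosome cells results in the
#' affected interaction contrasts being dropped, with a warning.
#'
#' @param records Tibble with columns `population`, `chrom`, `distance_bp`,
#'   `r2` (e.g. row-bound [ld_scan()] output across populations).
#' @return An object of class `ld_anova` wrapping the `lm` fit and its
#'   sequential ANOVA table; see [tidy.ld_anova()] and [glance.ld_anova()].
#' @export
ld_anova <- function(records) {
  d <- tibble::tibble(
    r2 = records$r2,
    population = factor(records$population),
    chromosome = factor(records$chrom),
    distance_bp = as.numeric(records$distance_bp)
  )
  if (nlevels(d$population) < 2) abort("need >= 2 populations")
  if (nlevels(d$chromosome) < 2) abort("need >= 2 chromosomes")
  # keep.order preserves the stated sequential order: population,
  # chromosome, interaction, then the distance covariate
  trms <- stats::terms(r2 ~ population + chromosome +
                         population:chromosome + distance_bp,
                       keep.order = TRUE)
  fit <- stats::lm(trms, data = d)
  if (anyNA(stats::coef(fit))) {
    warn("empty population x chromosome cells: affected interaction contrasts dropped")
  }
  tab <- stats::anova(fit)
  if (stats::df.residual(fit) <= 0) abort("no residual degrees of freedom")
  structure(list(fit = fit, anova = tab), class = "ld_anova")
}

#' @export
print.ld_anova <- function(x, ...) {
  cat("LD fixed-effects model: r2 ~ population + chromosome + interaction + distance\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the sequential ANOVA table of an LD model
#'
#' @param x An [ld_anova()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @method tidy ld_anova
#' @export
tidy.ld_anova <- function(x, ...) {
  tab <- x$anova
  tibble::tibble(
    term = rownames(tab),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
}

#' One-row summary of an LD model fit
#'
#' @param x An [ld_anova()] object.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `adj.r.squared`, `sigma`, `slope_bp`
#'   (the distance regression coefficient), `df.residual`, `nobs`.
#' @method glance ld_anova
#' @export
glance.ld_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    slope_bp = unname(stats::coef(x$fit)["distance_bp"]),
    df.residual = stats::df.residual(x$fit),
    nobs = stats::nobs(x$fit)
  )
}
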