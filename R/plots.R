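#' Plot an LD decay curve
#'
#' Mean r-squared per distance bin (bin upper edge on a log axis), one line
#' per population when present.
#'
#' @param object A `popld_decay` tibble from [decay_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot popld_decay
#' @export
autoplot.popld_decay <- function(object, ...) {
  d <- object[object$n_pairs > 0, ]
  aes <- if ("population" %in% names(d)) {
    ggplot2::aes(x = .data$bin_upper_kb, y = .data$mean_r2,
                 colour = .data$population, group = .data$population)
  } else {
    ggplot2::aes(x = .data$bin_upper_kb, y = .data$mean_r2, group = 1)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "marker interval (kb, bin upper edge)",
                  y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.popld_decay
#' @param decay A `popld_decay` tibble.
#' @export
plot_ld_decay <- function(decay, ...) autoplot.popld_decay(decay, ...)

#' Plot an effective-population-size trajectory
#'
#' Ne against generations ago (both axes log-scaled), one line per
#' population when present.
#'
#' @param object A `popld_ne` tibble from [ne_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot popld_ne
#' @export
autoplot.popld_ne <- function(object, ...) {
  aes <- if ("population" %in% names(object)) {
    ggplot2::aes(x = .data$t_generations, y = .data$ne,
                 colour = .data$population, group = .data$population)
  } else {
    ggplot2::aes(x = .data$t_generations, y = .data$ne, group = 1)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago (t = 1/2c)",
                  y = expression(N[e]),
                  title = "LD-based effective population size") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.popld_ne
#' @param ne A `popld_ne` tibble.
#' @export
plot_ne_trajectory <- function(ne, ...) autoplot.popld_ne(ne, ...)

#' Plot PCA sample coordinates
#'
#' @param object A `popld_pca` tibble from [pca_genotypes()].
#' @param components Two component names, default `c("PC1", "PC2")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot popld_pca
#' @export
autoplot.popld_pca <- function(object, components = c("PC1", "PC2"), ...) {
  ve <- attr(object, "var_explained")
  lab <- function(pc) {
    i <- as.integer(sub("PC", "", pc))
    if (!is.null(ve) && i <= length(ve)) {
      sprintf("%s (%.1f%%)", pc, 100 * ve[i])
    } else pc
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]],
    colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2]),
                  title = "Genotype PCA") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.popld_pca
#' @param pca A `popld_pca` tibble.
#' @export
plot_pca <- function(pca, ...) autoplot.popld_pca(pca, ...)

#' Plot a minor-allele-frequency spectrum
#'
#' @param object A `popld_maf_spectrum` tibble from [maf_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot popld_maf_spectrum
#' @export
autoplot.popld_maf_spectrum <- function(object, ...) {
  object$bin <- sprintf("(%.2f, %.2f]", object$bin_lower, object$bin_upper)
  object$bin <- factor(object$bin, levels = unique(object$bin))
  aes <- if ("population" %in% names(object)) {
    ggplot2::aes(x = .data$bin, y = .data$proportion, fill = .data$population)
  } else {
    ggplot2::aes(x = .data$bin, y = .data$proportion)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "minor allele frequency bin",
                  y = "proportion of markers",
                  title = "MAF spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.popld_maf_spectrum
#' @param spectrum A `popld_maf_spectrum` tibble.
#' @export
plot_maf_spectrum <- function(spectrum, ...) autoplot.popld_maf_spectrum(spectrum, ...)
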