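#' Plot a flank position-frequency matrix as an information-content logo
#'
#' Stacked per-position base contributions scaled by column information
#' content (bits), the text-logo analogue of a sequence logo.
#'
#' @param object A `spacer_pfm`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spacer_pfm <- function(object, ...) {
  df <- tidy(object)
  df <- mutate(df, bits = .data$frequency * .data$information)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = sprintf("%s flank position (guide-oriented 5'→3')",
                              object$side),
                  y = "information (bits)", fill = NULL,
                  title = sprintf("Flank composition, n = %d",
                                  object$n_sequences)) +
    ggplot2::theme_minimal()
}

#' Plot binned per-strand protospacer distributions
#'
#' Per-replicate proportions as bars split by strand, the smoothed
#' across-replicate mean as a line, and (when present) the motif
#' frequency track.
#'
#' @param object A `bin_counts` from [bin_distribution()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bin_counts <- function(object, ...) {
  bins <- mutate(object$bins,
                 strand_label = ifelse(.data$strand == "+", "F targets",
                                       "R targets"))
  sm <- mutate(object$smoothed,
               strand_label = ifelse(.data$strand == "+", "F targets",
                                     "R targets"))
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin,
                                          y = .data$proportion)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$replicate),
                      position = "dodge") +
    ggplot2::geom_line(data = sm,
                       ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::facet_wrap(~strand_label, ncol = 1) +
    ggplot2::labs(x = sprintf("genome bin (%s)", object$genome_id),
                  y = sprintf("proportion of targets (%s view)",
                              object$view)) +
    ggplot2::theme_minimal()
  if (!is.null(object$motif_track))
    p <- p + ggplot2::geom_line(data = object$motif_track,
                                ggplot2::aes(x = .data$bin,
                                             y = .data$frequency),
                                colour = "red")
  p
}

#' Plot a Monte-Carlo overlap null with the observed overlap
#'
#' Histogram of per-iteration overlap fractions, the fitted normal
#' density, and a vertical line at the observed fraction when present.
#'
#' @param object An `overlap_null` from [run_null()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.overlap_null <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70") +
    ggplot2::stat_function(fun = stats::dnorm,
                           args = list(mean = object$mu, sd = object$sigma),
                           colour = "steelblue") +
    ggplot2::labs(x = "overlap fraction with reference pool",
                  y = "density",
                  title = sprintf("%s sampling null (mu = %.3f, sd = %.3f)",
                                  object$mode, object$mu, object$sigma)) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed))
    p <- p + ggplot2::geom_vline(xintercept = object$observed,
                                 colour = "red", linetype = 2)
  p
}

#' Plot mRNA-targeting proportions against their binomial null bands
#'
#' @param tests Tibble from [mrna_proportions()].
#' @return A ggplot object.
#' @export
plot_mrna_proportions <- function(tests) {
  df <- filter(tests, !is.na(.data$proportion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_class,
                                   y = .data$proportion,
                                   colour = .data$replicate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$null_lower,
                                        ymax = .data$null_upper),
                           colour = "grey50", width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::facet_grid(.data$view ~ .data$locus_id) +
    ggplot2::labs(x = "target genome",
                  y = "proportion of mRNA-targeting spacers") +
    ggplot2::theme_minimal()
}
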