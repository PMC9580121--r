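#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a MAF spectrum
#' @param object a [maf_spectrum()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.maf_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$n_sites)) +
    ggplot2::geom_col(width = object$bin_high[1] - object$bin_low[1],
                      fill = "grey40") +
    ggplot2::labs(x = "minor allele frequency", y = "sites",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a per-site spectrum comparison
#' @param object a [spectrum_correlation()] result (per-site mode).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectrum_comparison <- function(object, ...) {
  if (is.null(object$pairs)) rlang::abort("no per-site pairs to plot (binned mode)")
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$maf_a, .data$maf_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "MAF, dataset A", y = "MAF, dataset B",
                  subtitle = sprintf("Pearson r = %.3f (n = %d shared sites)",
                                     object$pearson_r, object$n_shared)) +
    ggplot2::theme_minimal()
}

#' Plot LD decay over distance
#' @param decay output of [ld_decay()].
#' @return a ggplot.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes((.data$dist_low + .data$dist_high) / 2,
                                      .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.5) +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
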