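#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weighted density with its mode
#' @param object An `erf_density` from [weighted_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erf_density <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dashed") +
    ggplot2::labs(x = "value", y = "density",
                  subtitle = sprintf("mode = %.2f", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs experimental observables for a reweighting fit
#'
#' Prior and posterior ensemble means against the experimental values, with
#' the per-observable uncertainty as error bars.
#'
#' @param object An `erf_reweight`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erf_reweight <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, c("prior_mean", "posterior_mean"),
                              names_to = "ensemble", values_to = "predicted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experimental,
                                     y = .data$predicted,
                                     colour = .data$ensemble)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$experimental - .data$sigma,
                                         xmax = .data$experimental + .data$sigma),
                            height = 0, colour = "grey75") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "experimental", y = "ensemble mean") +
    ggplot2::theme_minimal()
}

#' Prior/posterior radius-of-gyration densities of a run report
#' @param object An `erf_report`.
#' @param ... Unused.
#' @return A ggplot with both densities and their modes.
#' @export
autoplot.erf_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(x = object$rgyr$prior$x, y = object$rgyr$prior$y,
                   ensemble = "prior"),
    tibble::tibble(x = object$rgyr$posterior$x, y = object$rgyr$posterior$y,
                   ensemble = "posterior"))
  modes <- tibble::tibble(
    ensemble = c("prior", "posterior"),
    mode = c(object$rgyr$prior_mode, object$rgyr$posterior_mode))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$ensemble)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = modes,
                        ggplot2::aes(xintercept = .data$mode,
                                     colour = .data$ensemble),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "radius of gyration [Angstrom]", y = "density") +
    ggplot2::theme_minimal()
}

#' Energy histogram with the fitted log-normal and coverage cutoff
#' @param scores Conformer scores.
#' @param fit An `erf_lognormal` fit of them.
#' @param cutoff Threshold from [coverage_cutoff()].
#' @return A ggplot.
#' @export
plot_energy_gate <- function(scores, fit, cutoff) {
  df <- tibble::tibble(score = scores)
  grid <- seq(min(scores), max(scores), length.out = 400)
  dens <- stats::dlnorm(grid - fit$shift, fit$mu, fit$sigma)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = tibble::tibble(x = grid, y = dens),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "score", y = "density") +
    ggplot2::theme_minimal()
}
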