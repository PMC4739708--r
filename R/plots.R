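# ggplot2 displays for the main result types.

#' Plot a binned, normalized time course
#'
#' @param binned Output of [bin_timeplot()].
#' @return A ggplot object: minute-average normalized response with SEM
#'   bars and a reference line at 1.
#' @export
plot_timeplot <- function(binned) {
  check_columns(binned, c("bin_start_s", "mean_norm", "sem_norm"), "binned")
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$bin_start_s / 60,
                               y = .data$mean_norm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_norm - .data$sem_norm,
                                        ymax = .data$mean_norm + .data$sem_norm),
                           width = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time (min)", y = "Normalized response",
                  title = "Baseline-normalized response time course") +
    ggplot2::theme_minimal()
}

#' @rdname run_mixing
#' @param object A `mixing_run` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixing_run <- function(object, ...) {
  p <- attr(object, "params")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$delta_n_pct)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_density(colour = "firebrick") +
    ggplot2::labs(
      x = "Simulated compound percent change (%)", y = "Density",
      title = sprintf("Input-mixing simulation (S = %g, %d SCRs)",
                      p$s, nrow(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a segregation sweep
#'
#' Variance of the simulated compound percent changes as a function of
#' the segregation parameter, with the reference variance as a dashed
#' line; points are filled where the simulated variance is significantly
#' below the reference.
#'
#' @param sweep Output of [sweep_segregation()].
#' @return A ggplot object.
#' @export
plot_segregation <- function(sweep) {
  check_columns(sweep, c("s", "var_delta", "variance_lower"), "sweep")
  ref <- attr(sweep, "reference_variance")
  gg <- ggplot2::ggplot(as_tibble(sweep),
                        ggplot2::aes(x = .data$s, y = .data$var_delta)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$variance_lower), size = 3) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      name = "Variance significantly\nbelow reference"
    ) +
    ggplot2::labs(x = "Segregation parameter S",
                  y = "Var of simulated percent change (%^2)",
                  title = "Distribution broadening with input segregation") +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    gg <- gg + ggplot2::geom_hline(yintercept = ref, linetype = "dashed")
  }
  gg
}

#' Overlay peak-normalized density estimates
#'
#' Gaussian kernel density estimates of several percent-change
#' distributions, each normalized to its peak for display.
#'
#' @param deltas Named list of numeric percent-change vectors.
#' @param bandwidth Optional common bandwidth.
#' @return A ggplot object.
#' @export
#' @examples
#' plot_delta_densities(list(a = rnorm(40, 0, 10), b = rnorm(40, 0, 35)))
plot_delta_densities <- function(deltas, bandwidth = NULL) {
  if (!is.list(deltas) || is.null(names(deltas)) ||
      any(names(deltas) == "")) {
    stop_param("`deltas` must be a named list of numeric vectors.")
  }
  df <- purrr::imap(deltas, function(x, nm) {
    kde <- gaussian_kde(x, bandwidth = bandwidth, normalize_peak = TRUE)
    tibble(dataset = nm, grid = kde$grid, density = kde$density)
  }) |>
    bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$density,
                                   colour = .data$dataset)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Percent change (%)",
                  y = "Density (peak-normalized)") +
    ggplot2::theme_minimal()
}

#' @rdname gaussian_kde
#' @param object A `kde_estimate` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.kde_estimate <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Value", y = "Density") +
    ggplot2::theme_minimal()
}
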