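#' Plot a calibration trace
#'
#' Two panels: the threshold trajectory (`sigma`, `tau` against calibration
#' step) and the measured prevalence with the `x_o +/- epsilon` acceptance
#' band.
#'
#' @param object A `frustration_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frustration_calibration
#' @export
autoplot.frustration_calibration <- function(object, ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(tr, cols = c("sigma", "tau", "x"),
                              names_to = "quantity", values_to = "value")
  band <- tibble(quantity = "x",
                 lo = object$spec$x_o - object$spec$epsilon,
                 hi = object$spec$x_o + object$spec$epsilon)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$j, y = .data$value)) +
    ggplot2::geom_rect(data = band, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "grey85") +
    ggplot2::geom_step(ggplot2::aes(colour = .data$quantity)) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "calibration step j", y = NULL,
                  title = "Threshold calibration trace") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the replicate prevalence distribution of an ensemble
#'
#' @param object A `frustration_ensemble` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frustration_ensemble
#' @export
autoplot.frustration_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = max(10, ceiling(sqrt(object$eta))),
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$x_bar, linetype = 2) +
    ggplot2::labs(x = "replicate prevalence x", y = "replicates",
                  title = sprintf("Ensemble prevalence (eta = %d): mean %.4f, sd %.4f",
                                  object$eta, object$x_bar, object$x_sd)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Mean prevalence against the swept fraction with a `+/-1` sd ribbon. For the
#' two-variant student-success sweep the variants are coloured; for the 3-D
#' factorial grid the slices are faceted by `rho_NE_S` and coloured by
#' `rho_NE`.
#'
#' @param object A `frustration_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frustration_sweep
#' @export
autoplot.frustration_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  dat <- dplyr::filter(tibble::as_tibble(object), .data$feasible)
  is_3d <- swept == "rho_E_S" && length(unique(dat$rho_NE)) > 1
  two_variant <- swept == "rho_E_S" && !is_3d && length(unique(dat$rho_NE_S)) > 1
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[swept]], y = .data$x_bar))
  if (is_3d) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(colour = .data$rho_NE,
                                      group = .data$rho_NE)) +
      ggplot2::facet_wrap(~rho_NE_S, labeller = ggplot2::label_both) +
      ggplot2::scale_colour_viridis_c()
  } else if (two_variant) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$x_bar - .data$x_sd,
                                        ymax = .data$x_bar + .data$x_sd,
                                        group = factor(.data$rho_NE_S)),
                           alpha = 0.15) +
      ggplot2::geom_line(ggplot2::aes(colour = factor(.data$rho_NE_S))) +
      ggplot2::labs(colour = "rho_NE_S")
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$x_bar - .data$x_sd,
                                        ymax = .data$x_bar + .data$x_sd),
                           alpha = 0.15) +
      ggplot2::geom_line() +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(y = "mean prevalence x_bar",
                    title = sprintf("Prevalence sweep over %s", swept)) +
    ggplot2::theme_minimal()
}
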