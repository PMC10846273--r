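#' Plot a coexistence sweep
#'
#' Coexistence cooperator fraction `x*` against the privatized fraction
#' `alpha`, one curve per release amount `r`.
#'
#' @param object A sweep tibble from [sweep_alpha_r()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sw <- sweep_alpha_r(coop_params(C = 0.1), seq(0.05, 0.6, by = 0.05),
#'                     c(0.5, 1, 2))
#' autoplot(sw)
#' @export
autoplot.coop_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$alpha, y = .data$x_star,
                               colour = factor(.data$r),
                               group = factor(.data$r))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(alpha ~ "(privatized fraction)"),
                  y = expression(x^"*" ~ "(coexistence cooperator fraction)"),
                  colour = "r") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a serial-transfer frequency trajectory
#'
#' @param object A trajectory tibble from [simulate_serial_transfers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data$x)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "cooperator frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic coevolution dataset
#'
#' Observed per-line cooperator frequencies (points and dashed lines, with
#' Wilson intervals) over the shared latent trajectory (solid line), the
#' layout of the replicate-trajectory figures of coevolution experiments.
#'
#' @param object A dataset tibble from [generate_coevolution_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_dataset <- function(object, ...) {
  est <- estimate_frequency(object)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_true), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_hat, group = .data$line_id,
                                    colour = .data$line_id),
                       linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$p_hat,
                                          ymin = .data$ci_low,
                                          ymax = .data$ci_high,
                                          colour = .data$line_id),
                             size = 0.2) +
    ggplot2::labs(x = "generation", y = "cooperator frequency",
                  colour = "line") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an observed-vs-fitted calibration
#'
#' @param object A `coop_fit` from [calibrate_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_fit), colour = "steelblue") +
    ggplot2::labs(x = "generation", y = "cooperator frequency",
                  title = if (object$identifiable) {
                    sprintf("fitted alpha = %.3g, C = %.3g",
                            object$alpha, object$C)
                  } else {
                    "non-identifiable trajectory"
                  }) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
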