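#' Plot pressure-flow and efficiency-flow curves
#'
#' Draws the HQ and etaQ characteristics of one or more performance curves,
#' coloured by design and faceted by field.
#'
#' @param curves A long curve tibble (multiple designs and/or speeds
#'   allowed).
#' @return A ggplot object.
#' @examples
#' crv <- simulate_curves(factorial_designs()[1:4, ], 20000)
#' plot_performance_curves(crv)
#' @export
plot_performance_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("dp_mmhg", "eta"),
                              names_to = "field", values_to = "value")
  long$field <- factor(long$field, c("dp_mmhg", "eta"),
                       c("pressure head [mmHg]", "efficiency [-]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q_lpm, y = .data$value,
                                     colour = .data$design_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "flow rate [L/min]", y = NULL, colour = "design") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scaled curve against its target operating point
#'
#' @param object A [scale_curve_to_op()] result.
#' @param ... Unused.
#' @return A ggplot object showing the rescaled HQ curve and the target
#'   point.
#' @method autoplot curve_scaling
#' @export
autoplot.curve_scaling <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$q_lpm, y = .data$dp_mmhg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = object$target$q_lpm,
                      y = object$target$dp_mmhg, colour = "red", size = 3,
                      shape = 4, stroke = 1.5) +
    ggplot2::labs(
      x = "flow rate [L/min]", y = "pressure head [mmHg]",
      title = sprintf("%s at %.0f rpm", object$target$label,
                      object$omega_scaled_rpm)
    ) +
    ggplot2::theme_minimal()
}

#' Parity plot of a surrogate against its training targets
#'
#' Predicted versus simulated design-point efficiency over the training
#' designs, the standard regression diagnostic for surrogate quality.
#'
#' @param object A fitted `pump_surrogate`.
#' @param data The [build_design_dataset()] it was trained on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pump_surrogate
#' @export
autoplot.pump_surrogate <- function(object, data, ...) {
  df <- tibble::tibble(
    target = data$eta_at_op,
    output = predict(object, data)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$output)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "simulated efficiency", y = "predicted efficiency",
                  title = sprintf("%s surrogate", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot the GA convergence history
#'
#' @param object A [ga_optimize()] result.
#' @param ... Unused.
#' @return A ggplot object of generation-best objective versus generation.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best objective (negated efficiency)") +
    ggplot2::theme_minimal()
}

#' Plot a camber line
#'
#' @param object A [camber_arc()].
#' @param ... Unused.
#' @return A ggplot object of the camber line in the blade-to-blade plane.
#' @method autoplot camber_arc
#' @export
autoplot.camber_arc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tangential [mm]", y = "axial [mm]") +
    ggplot2::theme_minimal()
}
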