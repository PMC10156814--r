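#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quartic pressure-flow fit
#'
#' @param x A [fit_quartic()] object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @method tidy quartic_fit
#' @export
tidy.quartic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.quartic_fit
#' @return `glance()`: a one-row tibble with `rmse_of_fit_mmhg`,
#'   `q_min_lpm`, `q_max_lpm`, `n`.
#' @method glance quartic_fit
#' @export
glance.quartic_fit <- function(x, ...) {
  tibble::tibble(rmse_of_fit_mmhg = x$rmse_of_fit,
                 q_min_lpm = x$valid_range[1], q_max_lpm = x$valid_range[2],
                 n = x$n)
}

#' Tidy a fitted surrogate
#'
#' `tidy()` returns the fitted quantities appropriate to the model kind:
#' regression coefficients (MLR), kernel hyperparameters (GPR) or the
#' weight vector with the evidence state (BRANN). `glance()` returns the
#' one-row metric summary on the natural efficiency scale.
#'
#' @param x A fitted `pump_surrogate`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pump_surrogate
#' @export
tidy.pump_surrogate <- function(x, ...) {
  if (inherits(x, "mlr_surrogate")) {
    tibble::tibble(term = names(x$coefficients),
                   estimate = unname(x$coefficients))
  } else if (inherits(x, "gpr_surrogate")) {
    hp <- x$hyperparameters[!is.na(x$hyperparameters)]
    tibble::tibble(term = names(hp), estimate = unname(hp))
  } else {
    tibble::tibble(term = c(sprintf("w%02d", seq_along(x$weights)),
                            "alpha", "beta", "gamma"),
                   estimate = c(x$weights, x$alpha, x$beta, x$gamma))
  }
}

#' @rdname tidy.pump_surrogate
#' @method glance pump_surrogate
#' @export
glance.pump_surrogate <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, n = x$n),
    tibble::as_tibble(x$metrics[purrr::map_lgl(x$metrics, ~ length(.x) == 1)])
  )
}

#' Tidy a GA result
#'
#' `tidy()` returns the generation-best fitness history; `glance()` the
#' one-row run summary.
#'
#' @param x A [ga_optimize()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$history

#' @rdname tidy.ga_result
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_fitness = x$best_fitness,
                   generations = x$generations, converged = x$converged,
                   feasible = x$feasibility$feasible, seed = x$seed),
    x$best_design[, DESIGN_PARAMS]
  )
}

#' Tidy a curve-scaling result
#'
#' `tidy()` returns the rescaled curve samples; `glance()` the scaling
#' summary (matched point, scaled speed, extrapolation flag).
#'
#' @param x A [scale_curve_to_op()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy curve_scaling
#' @export
tidy.curve_scaling <- function(x, ...) x$curve

#' @rdname tidy.curve_scaling
#' @method glance curve_scaling
#' @export
glance.curve_scaling <- function(x, ...) {
  tibble::tibble(label = x$target$label, q1_lpm = x$target$q_lpm,
                 dp1_mmhg = x$target$dp_mmhg, q2_lpm = x$q2_lpm,
                 dp2_mmhg = x$dp2_mmhg,
                 omega_scaled_rpm = x$omega_scaled_rpm,
                 extrapolated = x$extrapolated)
}

#' Tidy a GA repeatability study
#'
#' @param x A [ga_repeatability()] result.
#' @param ... Unused.
#' @return `tidy()`: per-parameter spread tibble; `glance()`: one-row
#'   summary.
#' @method tidy ga_repeatability
#' @export
tidy.ga_repeatability <- function(x, ...) x$spread

#' @rdname tidy.ga_repeatability
#' @method glance ga_repeatability
#' @export
glance.ga_repeatability <- function(x, ...) {
  tibble::tibble(n_repeats = length(x$best_fitness),
                 max_spread_pct = x$max_spread_pct,
                 tolerance_pct = x$tolerance_pct,
                 within_tolerance = x$within_tolerance,
                 non_identifiable = x$non_identifiable)
}
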