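#' Build the surrogate training dataset
#'
#' Pairs each design's five geometry parameters with its design-point
#' efficiency: the efficiency interpolated at the target flow on the
#' design's scaled etaQ curve. Because every curve has been scaled through
#' the target operating point, the rotational speed becomes intrinsic to the
#' geometry and the surrogate needs only the five geometric inputs. Feature
#' and target normalisation maps onto [-1, 1] (min-max over the included
#' designs) are stored with the dataset; a zero-span feature or target maps
#' to 0.
#'
#' @param designs A designs tibble.
#' @param scaled_curves A long tibble of scaled curve samples for those
#'   designs (each design's rows at its own scaled speed), e.g. from
#'   [run_baseline()] or by binding `scale_curve_to_op(...)$curve` results.
#' @param target_op The [operating_point()] the curves were scaled through.
#'
#' @return An object of class `design_dataset`: a tibble with `design_id`,
#'   the five parameter columns and `eta_at_op`, with attributes
#'   `normalisation` (per-feature and target min/max) and `excluded`
#'   (design ids whose scaled curve did not cover the target flow; these are
#'   dropped with a warning).
#' @examples
#' designs <- factorial_designs()[1:6, ]
#' curves <- simulate_curves(designs, 20000)
#' scaled <- dplyr::group_modify(
#'   dplyr::group_by(curves, design_id),
#'   ~ scale_curve_to_op(dplyr::mutate(.x, design_id = .y$design_id),
#'                       operating_point(2, 70))$curve[-1]
#' )
#' ds <- build_design_dataset(designs, dplyr::ungroup(scaled),
#'                            operating_point(2, 70))
#' @export
build_design_dataset <- function(designs, scaled_curves, target_op) {
  check_designs(designs)
  stopifnot(inherits(target_op, "operating_point"))
  eta <- purrr::map(designs$design_id, function(id) {
    crv <- dplyr::filter(scaled_curves, .data$design_id == id)
    if (nrow(crv) == 0) return(NULL)
    tryCatch(efficiency_at(crv, target_op$q_lpm),
             bladeforge_error_extrapolation = function(e) NULL)
  })
  keep <- !purrr::map_lgl(eta, is.null)
  if (!all(keep)) {
    rlang::warn(sprintf(
      "design-point flow outside the scaled curve range for: %s (excluded)",
      paste(designs$design_id[!keep], collapse = ", ")
    ))
  }
  data <- designs[keep, c("design_id", DESIGN_PARAMS)]
  data$eta_at_op <- purrr::flatten_dbl(eta[keep])
  norm <- list(
    features = tibble::tibble(
      parameter = DESIGN_PARAMS,
      min = purrr::map_dbl(DESIGN_PARAMS, ~ min(data[[.x]])),
      max = purrr::map_dbl(DESIGN_PARAMS, ~ max(data[[.x]]))
    ),
    target = c(min = min(data$eta_at_op), max = max(data$eta_at_op))
  )
  structure(data,
            normalisation = norm,
            excluded = designs$design_id[!keep],
            target_op = target_op,
            class = c("design_dataset", class(data)))
}

# affine [-1, 1] maps --------------------------------------------------------

norm_affine <- function(x, lo, hi) {
  span <- hi - lo
  if (span == 0) rep(0, length(x)) else 2 * (x - lo) / span - 1
}

denorm_affine <- function(z, lo, hi) {
  span <- hi - lo
  (z + 1) / 2 * span + lo
}

normalise_features <- function(designs, normalisation) {
  f <- normalisation$features
  m <- purrr::map(seq_along(DESIGN_PARAMS), function(j) {
    norm_affine(designs[[DESIGN_PARAMS[j]]], f$min[j], f$max[j])
  })
  mat <- do.call(cbind, m)
  colnames(mat) <- DESIGN_PARAMS
  mat
}

normalise_target <- function(eta, normalisation) {
  t <- normalisation$target
  norm_affine(eta, t[["min"]], t[["max"]])
}

denormalise_target <- function(z, normalisation) {
  t <- normalisation$target
  denorm_affine(z, t[["min"]], t[["max"]])
}

# natural-scale RMSE from normalised residuals
natural_rmse <- function(resid_norm, normalisation) {
  t <- normalisation$target
  sqrt(mean(resid_norm^2)) * (t[["max"]] - t[["min"]]) / 2
}

#' Multi-linear regression surrogate
#'
#' The least-squares benchmark surrogate: an ordinary least-squares linear
#' model with intercept on the five normalised geometry parameters. There is
#' no held-out set; the model is trained on, and its RMSE reported over, all
#' available designs (on the natural efficiency scale).
#'
#' @param data A [build_design_dataset()] object with more than 6 rows.
#' @return An object of class `c("mlr_surrogate", "pump_surrogate")` with
#'   normalised-scale `coefficients` and `metrics` (`rmse_all`).
#' @examples
#' # see build_design_dataset() for dataset construction
#' @export
fit_mlr <- function(data) {
  stopifnot(inherits(data, "design_dataset"))
  if (nrow(data) <= 6) abort_validation("fit_mlr needs more than 6 designs")
  norm <- attr(data, "normalisation")
  x <- cbind(`(Intercept)` = 1, normalise_features(data, norm))
  y <- normalise_target(data$eta_at_op, norm)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) abort_validation("design matrix is rank deficient")
  fit <- stats::lm.fit(x, y)
  structure(
    list(
      kind = "MLR",
      coefficients = fit$coefficients,
      normalisation = norm,
      metrics = list(rmse_all = natural_rmse(fit$residuals, norm)),
      n = nrow(data)
    ),
    class = c("mlr_surrogate", "pump_surrogate")
  )
}

#' Predict design-point efficiency with a surrogate
#'
#' Normalises the designs with the surrogate's stored training map,
#' evaluates the model and denormalises back to the natural efficiency
#' scale. Deterministic given the fitted state. Designs outside the training
#' box are still evaluated (the optimiser is allowed to extrapolate); use
#' [predict_design_eta()] for an explicit extrapolation flag.
#'
#' @param object A fitted surrogate.
#' @param newdata A designs tibble.
#' @param ... Unused.
#' @return A numeric vector of predicted efficiencies.
#' @export
predict.pump_surrogate <- function(object, newdata, ...) {
  check_designs(newdata, require_beta_order = FALSE)
  z <- surrogate_eval(object, normalise_features(newdata, object$normalisation))
  denormalise_target(z, object$normalisation)
}

surrogate_eval <- function(object, xnorm) UseMethod("surrogate_eval")

#' @export
surrogate_eval.mlr_surrogate <- function(object, xnorm) {
  drop(cbind(1, xnorm) %*% object$coefficients)
}

#' Predict with an extrapolation flag
#'
#' As [predict.pump_surrogate()], returned as a tibble with an
#' `extrapolating` column marking designs whose normalised features fall
#' outside the [-1, 1] training box.
#'
#' @inheritParams predict.pump_surrogate
#' @return A tibble with `design_id`, `eta_pred`, `extrapolating`.
#' @export
predict_design_eta <- function(object, newdata) {
  xn <- normalise_features(newdata, object$normalisation)
  tibble::tibble(
    design_id = newdata$design_id,
    eta_pred = predict(object, newdata),
    extrapolating = apply(abs(xn) > 1 + 1e-12, 1, any)
  )
}

#' @export
print.pump_surrogate <- function(x, ...) {
  cat(sprintf("<%s surrogate> trained on %d designs\n", x$kind, x$n))
  m <- x$metrics
  for (nm in names(m)) {
    if (is.numeric(m[[nm]]) && length(m[[nm]]) == 1) {
      cat(sprintf("  %s: %.4g\n", nm, m[[nm]]))
    }
  }
  invisible(x)
}
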