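#' Define an operating point
#'
#' A clinical operating point is a (flow, pressure head) target such as
#' 2 L/min at 70 mmHg for the largest patients in the paediatric range.
#'
#' @param q_lpm Flow rate in L/min (> 0).
#' @param dp_mmhg Pressure head in mmHg (> 0).
#' @param label Optional label; defaults to `"OP_<q>L/min"`.
#' @return An object of class `operating_point`.
#' @examples
#' operating_point(2, 70)
#' @export
operating_point <- function(q_lpm, dp_mmhg, label = NULL) {
  if (!is.finite(q_lpm) || q_lpm <= 0 || !is.finite(dp_mmhg) || dp_mmhg <= 0) {
    abort_validation("operating point flow and pressure must be positive")
  }
  if (is.null(label)) label <- sprintf("OP_%gL/min", q_lpm)
  structure(list(q_lpm = q_lpm, dp_mmhg = dp_mmhg, label = label),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> %s: %g L/min @ %g mmHg\n",
              x$label, x$q_lpm, x$dp_mmhg))
  invisible(x)
}

check_curve <- function(curve, min_samples = 2) {
  need <- c("q_lpm", "dp_mmhg", "eta")
  miss <- setdiff(need, names(curve))
  if (length(miss) > 0) {
    abort_validation(paste0("curve is missing columns: ", paste(miss, collapse = ", ")))
  }
  if ("design_id" %in% names(curve) && length(unique(curve$design_id)) > 1) {
    abort_validation("curve must contain a single design_id")
  }
  if ("omega_rpm" %in% names(curve) && length(unique(curve$omega_rpm)) > 1) {
    abort_validation("curve must contain a single rotational speed")
  }
  if (nrow(curve) < min_samples) {
    abort_validation(sprintf("curve needs at least %d samples", min_samples))
  }
  if (is.unsorted(curve$q_lpm, strictly = TRUE)) {
    abort_validation("curve flow rates must be strictly increasing")
  }
  if (any(!is.finite(curve$eta)) || any(!is.finite(curve$dp_mmhg))) {
    abort_validation("curve samples must be finite")
  }
  invisible(curve)
}

curve_omega <- function(curve) {
  if (!"omega_rpm" %in% names(curve)) {
    abort_validation("curve has no omega_rpm column")
  }
  unique(curve$omega_rpm)[1]
}

#' Fit a quartic polynomial to a pressure-flow curve
#'
#' Ordinary least squares fit of
#' `dP = c1 Q^4 + c2 Q^3 + c3 Q^2 + c4 Q + c5` to the sampled HQ curve,
#' the parametric form used to locate the similitude match point on the
#' curve. Only the pressure head is ever polynomial-fitted; efficiency is
#' always interpolated linearly.
#'
#' @param curve A performance-curve tibble (columns `q_lpm`, `dp_mmhg`,
#'   `eta`; at least 5 samples with distinct flows).
#' @return An object of class `quartic_fit` with fields `coefficients`
#'   (named `c1`..`c5`, mmHg/L/min units), `rmse_of_fit` (mmHg, in-sample),
#'   `valid_range` (range of training flows, L/min) and `n`.
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' fit_quartic(crv)
#' @export
fit_quartic <- function(curve) {
  check_curve(curve, min_samples = 5)
  if (anyDuplicated(curve$q_lpm)) {
    abort_validation("duplicate flow values make the quartic fit rank deficient")
  }
  q <- curve$q_lpm
  fit <- stats::lm(dp_mmhg ~ I(q^4) + I(q^3) + I(q^2) + q, data = curve)
  if (any(is.na(stats::coef(fit)))) {
    abort_validation("quartic fit is rank deficient")
  }
  co <- stats::coef(fit)
  coefficients <- stats::setNames(
    c(co[["I(q^4)"]], co[["I(q^3)"]], co[["I(q^2)"]], co[["q"]],
      co[["(Intercept)"]]),
    paste0("c", 1:5)
  )
  structure(
    list(
      coefficients = coefficients,
      rmse_of_fit = sqrt(mean(stats::resid(fit)^2)),
      valid_range = range(q),
      n = length(q)
    ),
    class = "quartic_fit"
  )
}

#' Evaluate a quartic pressure-flow fit
#'
#' @param fit A [fit_quartic()] object.
#' @param q_lpm Flow rates (L/min) at which to evaluate.
#' @return Pressure head in mmHg.
#' @export
predict_quartic <- function(fit, q_lpm) {
  stopifnot(inherits(fit, "quartic_fit"))
  c_ <- fit$coefficients
  c_[1] * q_lpm^4 + c_[2] * q_lpm^3 + c_[3] * q_lpm^2 + c_[4] * q_lpm + c_[5]
}

#' @export
print.quartic_fit <- function(x, ...) {
  cat(sprintf(
    "<quartic_fit> dP = %.4g Q^4 + %.4g Q^3 + %.4g Q^2 + %.4g Q + %.4g\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3],
    x$coefficients[4], x$coefficients[5]
  ))
  cat(sprintf("  in-sample RMSE %.3g mmHg on Q in [%g, %g] L/min (n = %d)\n",
              x$rmse_of_fit, x$valid_range[1], x$valid_range[2], x$n))
  invisible(x)
}

#' Dimensionless flow and pressure coefficients
#'
#' Computes the flow coefficient `phi = Q / (omega D^3)` and the pressure
#' coefficient `psi = dP / (rho omega^2 D^2)` in SI units (omega in rad/s,
#' Q in m^3/s, dP in Pa, D the reference diameter). Geometrically similar
#' operating points share (phi, psi); this is the basis of the similitude
#' scaling.
#'
#' @param q_lpm Flow in L/min.
#' @param dp_mmhg Pressure head in mmHg.
#' @param omega_rpm Speed in rpm (> 0).
#' @param constants A [pump_constants()] object.
#' @return A tibble with columns `phi` and `psi`.
#' @examples
#' phi_psi(2, 70, 20000)
#' @export
phi_psi <- function(q_lpm, dp_mmhg, omega_rpm, constants = pump_constants()) {
  if (any(omega_rpm <= 0)) abort_validation("omega_rpm must be positive")
  w <- rpm_to_rads(omega_rpm)
  d <- constants$reference_diameter_mm * MM_TO_M
  tibble::tibble(
    phi = lpm_to_m3s(q_lpm) / (w * d^3),
    psi = mmhg_to_pa(dp_mmhg) / (constants$density * w^2 * d^2)
  )
}

#' Locate the similitude match point on a fitted curve
#'
#' Finds the flow `Q2` on the fitted source curve that shares the
#' dimensionless coefficients with the target operating point
#' `(Q1, dP1)`. Equating the affinity parabola `dP = dP1 (Q/Q1)^2` with the
#' quartic curve gives
#' `c1 Q2^4 + c2 Q2^3 + (c3 - dP1/Q1^2) Q2^2 + c4 Q2 + c5 = 0`,
#' solved exactly through the polynomial companion matrix. Real positive
#' roots inside the fit's valid range are preferred; among several the one
#' nearest `Q1` is chosen with a warning; if only out-of-range positive
#' roots exist the nearest to the range is taken and flagged as
#' extrapolated, with a warning. No real positive root is an error.
#'
#' @param fit A [fit_quartic()] object.
#' @param target An [operating_point()].
#' @return A list with `q2_lpm`, `dp2_mmhg` (on the fitted curve),
#'   `extrapolated` flag and `roots` (all real positive candidate roots).
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' match_operating_point(fit_quartic(crv), operating_point(2, 70))
#' @export
match_operating_point <- function(fit, target) {
  stopifnot(inherits(fit, "quartic_fit"), inherits(target, "operating_point"))
  c_ <- fit$coefficients
  coefs_asc <- c(c_[5], c_[4], c_[3] - target$dp_mmhg / target$q_lpm^2,
                 c_[2], c_[1])
  # drop trailing zero coefficients so polyroot sees the true degree
  deg <- max(which(abs(coefs_asc) > 0))
  if (deg < 2) {
    rlang::abort("degenerate match polynomial (constant)",
                 class = "bladeforge_error_no_root")
  }
  roots <- polyroot(coefs_asc[1:deg])
  real <- Re(roots)[abs(Im(roots)) < 1e-9 * pmax(1, abs(Re(roots)))]
  pos <- sort(real[real > 0])
  if (length(pos) == 0) {
    rlang::abort(
      sprintf("no real positive intersection between the curve and the affinity parabola (roots: %s)",
              paste(format(roots, digits = 4), collapse = ", ")),
      class = "bladeforge_error_no_root"
    )
  }
  lo <- fit$valid_range[1]
  hi <- fit$valid_range[2]
  tol <- 1e-8 * (hi - lo)
  in_range <- pos[pos >= lo - tol & pos <= hi + tol]
  if (length(in_range) >= 1) {
    if (length(in_range) > 1) {
      rlang::warn(sprintf(
        "multiple in-range intersections (%s); choosing the one nearest Q1 = %g",
        paste(format(in_range, digits = 6), collapse = ", "), target$q_lpm
      ))
    }
    q2 <- in_range[which.min(abs(in_range - target$q_lpm))]
    extrapolated <- FALSE
  } else {
    dist <- pmax(lo - pos, pos - hi)
    q2 <- pos[which.min(dist)]
    extrapolated <- TRUE
    rlang::warn(sprintf(
      "intersection Q2 = %.4g L/min lies outside the fitted range [%g, %g]; extrapolating",
      q2, lo, hi
    ))
  }
  list(q2_lpm = q2, dp2_mmhg = unname(predict_quartic(fit, q2)),
       extrapolated = extrapolated, roots = pos)
}

#' Affinity-scaled rotational speed
#'
#' At fixed diameter, equal flow coefficients require
#' `omega1 = omega2 * Q1 / Q2`: the speed at which the source curve passes
#' through the target operating point, given the match flow `Q2` on the
#' source curve.
#'
#' @param omega2_rpm Source-curve speed in rpm.
#' @param q1_lpm Target flow (L/min).
#' @param q2_lpm Matched flow on the source curve (L/min, > 0).
#' @return Scaled speed in rpm.
#' @examples
#' scaled_speed(20000, 2, 2.5) # 16000
#' @export
scaled_speed <- function(omega2_rpm, q1_lpm, q2_lpm) {
  if (any(q2_lpm <= 0)) abort_validation("q2_lpm must be positive")
  omega2_rpm * q1_lpm / q2_lpm
}

#' Rescale a performance curve to a new speed
#'
#' Applies the affinity laws sample-wise: flow scales with the speed ratio,
#' pressure head with its square, and efficiency is invariant at
#' corresponding flow coefficients.
#'
#' @param curve A performance-curve tibble with an `omega_rpm` column.
#' @param omega_new_rpm New speed in rpm (> 0).
#' @return The rescaled curve tibble.
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' rescale_curve(crv, 15000)
#' @export
rescale_curve <- function(curve, omega_new_rpm) {
  check_curve(curve)
  if (!is.finite(omega_new_rpm) || omega_new_rpm <= 0) {
    abort_validation("omega_new_rpm must be positive")
  }
  r <- omega_new_rpm / curve_omega(curve)
  dplyr::mutate(curve,
                q_lpm = .data$q_lpm * r,
                dp_mmhg = .data$dp_mmhg * r^2,
                omega_rpm = omega_new_rpm)
}

#' Scale a curve through a target operating point
#'
#' The full similitude-scaling operation: fit the quartic to the source HQ
#' curve, locate the match point sharing the target's dimensionless
#' coefficients, compute the scaled speed and rescale the whole curve (HQ
#' and etaQ) to it, so the scaled curve passes through the target operating
#' point.
#'
#' @param curve A performance-curve tibble at the source speed.
#' @param target An [operating_point()].
#' @return An object of class `curve_scaling`: a list with `omega_scaled_rpm`,
#'   `q2_lpm`, `dp2_mmhg`, `extrapolated`, `fit` (the [fit_quartic()]
#'   object), `target` and `curve` (the rescaled tibble).
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' sc <- scale_curve_to_op(crv, operating_point(2, 70))
#' sc$omega_scaled_rpm
#' @export
scale_curve_to_op <- function(curve, target) {
  fit <- fit_quartic(curve)
  m <- match_operating_point(fit, target)
  omega1 <- scaled_speed(curve_omega(curve), target$q_lpm, m$q2_lpm)
  structure(
    list(
      omega_scaled_rpm = omega1,
      q2_lpm = m$q2_lpm,
      dp2_mmhg = m$dp2_mmhg,
      extrapolated = m$extrapolated,
      fit = fit,
      target = target,
      curve = rescale_curve(curve, omega1)
    ),
    class = "curve_scaling"
  )
}

#' @export
print.curve_scaling <- function(x, ...) {
  cat(sprintf(
    "<curve_scaling> %s matched at Q2 = %.4g L/min (dP2 = %.4g mmHg): omega = %.0f rpm%s\n",
    x$target$label, x$q2_lpm, x$dp2_mmhg, x$omega_scaled_rpm,
    if (x$extrapolated) " [extrapolated]" else ""
  ))
  invisible(x)
}

#' Interpolate efficiency at a flow rate
#'
#' Piecewise-linear interpolation of the etaQ curve. Queries outside the
#' sampled flow range raise an error; there is no silent extrapolation.
#'
#' @param curve A performance-curve tibble.
#' @param q_lpm Flow rate(s) in L/min within the sampled range.
#' @return Interpolated efficiency value(s).
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' efficiency_at(crv, 2)
#' @export
efficiency_at <- function(curve, q_lpm) {
  check_curve(curve)
  rng <- range(curve$q_lpm)
  if (any(q_lpm < rng[1]) || any(q_lpm > rng[2])) {
    rlang::abort(
      sprintf("flow %s outside the sampled range [%g, %g] L/min",
              paste(format(q_lpm[q_lpm < rng[1] | q_lpm > rng[2]]), collapse = ", "),
              rng[1], rng[2]),
      class = "bladeforge_error_extrapolation"
    )
  }
  stats::approx(curve$q_lpm, curve$eta, xout = q_lpm)$y
}

#' Root-mean-square difference between two curves
#'
#' Compares a chosen field of two performance curves on curve `a`'s flow
#' grid restricted to the overlap of the two sampled ranges; curve `b` is
#' linearly interpolated onto that grid.
#'
#' @param a,b Performance-curve tibbles.
#' @param field `"dp_mmhg"` or `"eta"`.
#' @return The RMS difference (mmHg for pressure, dimensionless for
#'   efficiency).
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' curve_rmse(crv, crv, "dp_mmhg") # 0
#' @export
curve_rmse <- function(a, b, field = c("dp_mmhg", "eta")) {
  field <- match.arg(field)
  check_curve(a)
  check_curve(b)
  lo <- max(min(a$q_lpm), min(b$q_lpm))
  hi <- min(max(a$q_lpm), max(b$q_lpm))
  keep <- a$q_lpm >= lo & a$q_lpm <= hi
  if (lo > hi || !any(keep)) {
    abort_validation("curves have no overlapping flow range to compare")
  }
  qa <- a$q_lpm[keep]
  bi <- stats::approx(b$q_lpm, b[[field]], xout = qa)$y
  sqrt(mean((a[[field]][keep] - bi)^2))
}

#' Dimensionless specific speed
#'
#' `N_s = omega sqrt(Q) / (g H)^(3/4)` with omega in rad/s, Q in m^3/s and
#' the head `H = dP / (rho g)` in metres, the shape parameter placing a
#' machine on the axial-to-radial spectrum of a Cordier diagram.
#'
#' @param omega_rpm Speed in rpm.
#' @param op An [operating_point()].
#' @param constants A [pump_constants()] object.
#' @return Dimensionless specific speed.
#' @examples
#' specific_speed(15000, operating_point(2, 70)) # about 1.762
#' @export
specific_speed <- function(omega_rpm, op, constants = pump_constants()) {
  if (omega_rpm <= 0) abort_validation("omega_rpm must be positive")
  w <- rpm_to_rads(omega_rpm)
  gh <- mmhg_to_pa(op$dp_mmhg) / constants$density # g * H
  w * sqrt(lpm_to_m3s(op$q_lpm)) / gh^0.75
}

#' Rotational Reynolds number
#'
#' `Re = omega D^2 rho / mu` with omega in rad/s and D the reference
#' diameter, the tip-speed-based estimate of the flow regime in the rotating
#' section.
#'
#' @param omega_rpm Speed in rpm (>= 0).
#' @param constants A [pump_constants()] object.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_rotational(20000) # about 37000
#' @export
reynolds_rotational <- function(omega_rpm, constants = pump_constants()) {
  if (any(omega_rpm < 0)) abort_validation("omega_rpm must be non-negative")
  d <- constants$reference_diameter_mm * MM_TO_M
  rpm_to_rads(omega_rpm) * d^2 * constants$density / constants$viscosity
}
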