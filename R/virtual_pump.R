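#' Simulate performance curves with the analytic mean-line pump model
#'
#' Evaluates an affinity-exact mean-line model of the axial pump for one
#' blade design over a grid of flow rates at a fixed rotational speed,
#' returning the pressure-flow (HQ) and efficiency-flow (etaQ) samples. The
#' model works at the mid-span radius: with blade speed `U = omega * r_mid`
#' and axial velocity `c_x = Q / A` (A the annulus area), the slipped exit
#' swirl is `c_theta = sigma_s * (U - c_x * cot(beta2))` and the head is the
#' Euler head `rho * U * c_theta` minus an impeller incidence loss
#' `k_inc * rho/2 * (U - c_x cot(beta1))^2`, a diffuser incidence loss
#' `k_dif * rho/2 * (c_theta - c_x cot(alpha2))^2` and a chord-proportional
#' friction loss `k_fric * (cl_imp + cl_diff)/c_ref * rho/2 * (c_x^2 + U^2)`.
#' Shaft power is `rho * Q * U * c_theta + k_par * rho * omega^3 * r_mid^5`
#' and the hydraulic efficiency is `eta = Q * dP / P`, reported raw (it may
#' be negative or non-monotone off-design). Every head term is homogeneous
#' of degree 2 and the power of degree 3 in `(omega, Q)`, so the model obeys
#' the turbomachinery affinity laws exactly: `psi` and `eta` are functions
#' of the flow coefficient `phi` alone.
#'
#' @param design A single-row designs tibble (see [blade_design()]).
#' @param omega_rpm Rotational speed in rpm (> 0).
#' @param flow_lpm Strictly increasing vector of positive flow rates in
#'   L/min; default 0.5 to 4 L/min in steps of 0.5.
#' @param constants A [pump_constants()] object.
#' @param losses A [loss_coefficients()] object.
#' @param noise_sd Optional i.i.d. Gaussian noise standard deviation (mmHg)
#'   added to the pressure head only, to mimic simulation scatter; `seed` is
#'   required when positive.
#' @param seed Integer seed, required when `noise_sd > 0`.
#'
#' @return A tibble with columns `design_id`, `omega_rpm`, `q_lpm`,
#'   `dp_mmhg`, `eta` (one row per flow rate).
#' @examples
#' d <- blade_design(32.5, 82.5, 32.5, 11.5, 11.5)
#' simulate_curve(d, omega_rpm = 20000)
#' @export
simulate_curve <- function(design, omega_rpm,
                           flow_lpm = seq(0.5, 4, by = 0.5),
                           constants = pump_constants(),
                           losses = loss_coefficients(),
                           noise_sd = 0, seed = NULL) {
  check_designs(design)
  if (nrow(design) != 1) {
    abort_validation("simulate_curve() takes a single design; see simulate_curves()")
  }
  if (!is.finite(omega_rpm) || omega_rpm <= 0) {
    abort_validation("omega_rpm must be positive")
  }
  if (length(flow_lpm) < 1 || any(!is.finite(flow_lpm)) || any(flow_lpm <= 0) ||
      is.unsorted(flow_lpm, strictly = TRUE)) {
    abort_validation("flow_lpm must be strictly increasing and positive")
  }
  if (noise_sd < 0) abort_validation("noise_sd must be non-negative")
  if (noise_sd > 0 && is.null(seed)) {
    abort_validation("seed is required when noise_sd > 0")
  }

  rho <- constants$density
  rm <- r_mid_m(constants)
  area <- annulus_area_m2(constants)
  w <- rpm_to_rads(omega_rpm)
  U <- w * rm
  q_si <- lpm_to_m3s(flow_lpm)
  cx <- q_si / area

  cot_b1 <- cot_deg(design$beta1_deg)
  cot_b2 <- cot_deg(design$beta2_deg)
  cot_a2 <- cot_deg(design$alpha2_deg)

  c_theta <- losses$slip_factor * (U - cx * cot_b2)
  dp_pa <- rho * U * c_theta -
    losses$k_inc * 0.5 * rho * (U - cx * cot_b1)^2 -
    losses$k_dif * 0.5 * rho * (c_theta - cx * cot_a2)^2 -
    losses$k_fric * ((design$cl_imp_mm + design$cl_diff_mm) / losses$c_ref_mm) *
      0.5 * rho * (cx^2 + U^2)
  power <- rho * q_si * U * c_theta + losses$k_par * rho * w^3 * rm^5
  eta <- q_si * dp_pa / power

  dp_mmhg <- pa_to_mmhg(dp_pa)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    dp_mmhg <- dp_mmhg + stats::rnorm(length(dp_mmhg), sd = noise_sd)
  }

  tibble::tibble(
    design_id = design$design_id,
    omega_rpm = omega_rpm,
    q_lpm = flow_lpm,
    dp_mmhg = dp_mmhg,
    eta = eta
  )
}

#' Simulate curves for many designs
#'
#' Applies [simulate_curve()] to every row of a designs tibble at a common
#' speed and flow grid, binding the samples into one long tibble.
#'
#' @inheritParams simulate_curve
#' @param designs A designs tibble; the `feasible` column, if present, must
#'   be all `TRUE`.
#' @return A long tibble of curve samples (`design_id`, `omega_rpm`,
#'   `q_lpm`, `dp_mmhg`, `eta`).
#' @examples
#' simulate_curves(factorial_designs()[1:2, ], omega_rpm = 20000)
#' @export
simulate_curves <- function(designs, omega_rpm,
                            flow_lpm = seq(0.5, 4, by = 0.5),
                            constants = pump_constants(),
                            losses = loss_coefficients(),
                            noise_sd = 0, seed = NULL) {
  if ("feasible" %in% names(designs) && !all(designs$feasible)) {
    abort_validation("designs contain infeasible rows (beta2 <= beta1)")
  }
  seeds <- if (noise_sd > 0) seed + seq_len(nrow(designs)) - 1 else
    vector("list", nrow(designs))
  purrr::map2_dfr(
    seq_len(nrow(designs)), seeds,
    function(i, s) {
      simulate_curve(designs[i, c("design_id", DESIGN_PARAMS)], omega_rpm,
                     flow_lpm, constants, losses, noise_sd,
                     seed = if (noise_sd > 0) s else NULL)
    }
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
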