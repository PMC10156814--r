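#' Fixed pump constants
#'
#' Geometric and fluid constants of the pump that are held fixed during blade
#' optimisation: the annulus radii, tip gap, blade thickness and counts, the
#' diffuser outlet angle (always 90 degrees from tangential, i.e. swirl-free
#' outflow), blood density and viscosity, and the reference diameter used in
#' the dimensionless flow and pressure coefficients.
#'
#' @param hub_radius_mm Hub radius in mm.
#' @param shroud_radius_mm Shroud (casing) radius in mm.
#' @param tip_gap_um Impeller tip gap in micrometres (stored only; the
#'   mean-line model carries no tip-leakage term).
#' @param blade_thickness_mm Constant blade thickness in mm (stored only).
#' @param n_impeller_blades,n_diffuser_blades Blade counts.
#' @param density Blood density in kg/m^3.
#' @param viscosity Blood dynamic viscosity in Pa.s.
#'
#' @return An object of class `pump_constants`: a named list with the above
#'   fields plus `diffuser_outlet_angle_deg` (fixed 90) and
#'   `reference_diameter_mm` (always `2 * shroud_radius_mm`).
#' @examples
#' pump_constants()
#' @export
pump_constants <- function(hub_radius_mm = 1.0,
                           shroud_radius_mm = 3.85,
                           tip_gap_um = 100,
                           blade_thickness_mm = 0.5,
                           n_impeller_blades = 2,
                           n_diffuser_blades = 3,
                           density = 1050,
                           viscosity = 0.0035) {
  if (hub_radius_mm <= 0 || shroud_radius_mm <= 0 || tip_gap_um <= 0 ||
      blade_thickness_mm <= 0 || density <= 0 || viscosity <= 0) {
    abort_validation("all pump constants must be positive")
  }
  if (hub_radius_mm >= shroud_radius_mm) {
    abort_validation("hub_radius_mm must be smaller than shroud_radius_mm")
  }
  structure(
    list(
      hub_radius_mm = hub_radius_mm,
      shroud_radius_mm = shroud_radius_mm,
      tip_gap_um = tip_gap_um,
      blade_thickness_mm = blade_thickness_mm,
      n_impeller_blades = n_impeller_blades,
      n_diffuser_blades = n_diffuser_blades,
      diffuser_outlet_angle_deg = 90,
      density = density,
      viscosity = viscosity,
      reference_diameter_mm = 2 * shroud_radius_mm
    ),
    class = "pump_constants"
  )
}

#' @export
print.pump_constants <- function(x, ...) {
  cat("<pump_constants>\n")
  cat(sprintf("  annulus: hub %.2f mm, shroud %.2f mm (D = %.2f mm)\n",
              x$hub_radius_mm, x$shroud_radius_mm, x$reference_diameter_mm))
  cat(sprintf("  blades: %d impeller + %d diffuser, thickness %.2f mm, tip gap %g um\n",
              x$n_impeller_blades, x$n_diffuser_blades,
              x$blade_thickness_mm, x$tip_gap_um))
  cat(sprintf("  blood: rho = %g kg/m^3, mu = %g Pa.s\n", x$density, x$viscosity))
  invisible(x)
}

# mid-span radius in metres
r_mid_m <- function(constants) {
  (constants$hub_radius_mm + constants$shroud_radius_mm) / 2 * MM_TO_M
}

# annulus flow area in m^2
annulus_area_m2 <- function(constants) {
  pi * ((constants$shroud_radius_mm * MM_TO_M)^2 -
          (constants$hub_radius_mm * MM_TO_M)^2)
}

#' Loss coefficients of the analytic pump model
#'
#' Coefficients of the mean-line loss model used by [simulate_curve()]. The
#' model charges the Euler head with an impeller incidence loss, a diffuser
#' incidence loss and a chord-proportional friction loss, and adds a parasitic
#' (disc-friction-like) term to the shaft power. All coefficients are exposed
#' so that tests and studies can fix them.
#'
#' @param slip_factor Slip factor applied to the ideal exit swirl, in (0, 1].
#' @param k_inc Impeller incidence-loss coefficient (dimensionless, >= 0).
#' @param k_dif Diffuser incidence-loss coefficient (dimensionless, >= 0).
#' @param k_fric Friction-loss coefficient per unit total chord (>= 0).
#' @param k_par Parasitic power coefficient multiplying rho * omega^3 * r_mid^5.
#' @param c_ref_mm Reference total chord in mm used to non-dimensionalise the
#'   friction loss.
#'
#' @return An object of class `loss_coefficients`.
#' @examples
#' loss_coefficients()
#' @export
loss_coefficients <- function(slip_factor = 0.85,
                              k_inc = 0.6,
                              k_dif = 0.6,
                              k_fric = 0.04,
                              k_par = 1.0,
                              c_ref_mm = 23) {
  vals <- c(slip_factor, k_inc, k_dif, k_fric, k_par, c_ref_mm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_validation("loss coefficients must be finite and non-negative")
  }
  if (slip_factor <= 0 || slip_factor > 1) {
    abort_validation("slip_factor must lie in (0, 1]")
  }
  structure(
    list(slip_factor = slip_factor, k_inc = k_inc, k_dif = k_dif,
         k_fric = k_fric, k_par = k_par, c_ref_mm = c_ref_mm),
    class = "loss_coefficients"
  )
}

#' @export
print.loss_coefficients <- function(x, ...) {
  cat("<loss_coefficients>\n")
  cat(sprintf("  slip %.2f | k_inc %.2f | k_dif %.2f | k_fric %.3f | k_par %.2f | c_ref %.1f mm\n",
              x$slip_factor, x$k_inc, x$k_dif, x$k_fric, x$k_par, x$c_ref_mm))
  invisible(x)
}
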