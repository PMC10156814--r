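DESIGN_PARAMS <- c("beta1_deg", "beta2_deg", "alpha2_deg", "cl_imp_mm", "cl_diff_mm")

#' Construct a tibble of blade designs
#'
#' A blade design is described by five governing parameters: the impeller
#' inlet and outlet angles `beta1_deg` and `beta2_deg`, the diffuser inlet
#' angle `alpha2_deg` (all measured in degrees from the tangential direction)
#' and the impeller and diffuser chord lengths `cl_imp_mm` and `cl_diff_mm`
#' in mm. Angles must lie in (0, 90], chords must be positive, and the
#' impeller outlet angle must exceed the inlet angle so the blade is
#' correctly oriented.
#'
#' @param beta1_deg,beta2_deg Impeller inlet/outlet blade angles (deg from
#'   tangential).
#' @param alpha2_deg Diffuser inlet blade angle (deg from tangential).
#' @param cl_imp_mm,cl_diff_mm Impeller and diffuser chord lengths (mm).
#' @param design_id Optional character ids; defaults to `d01`, `d02`, ...
#'
#' @return A tibble with columns `design_id`, `beta1_deg`, `beta2_deg`,
#'   `alpha2_deg`, `cl_imp_mm`, `cl_diff_mm`.
#' @examples
#' blade_design(25, 90, 32.5, 11, 11)
#' @export
blade_design <- function(beta1_deg, beta2_deg, alpha2_deg,
                         cl_imp_mm, cl_diff_mm, design_id = NULL) {
  n <- length(beta1_deg)
  if (is.null(design_id)) design_id <- sprintf("d%02d", seq_len(n))
  d <- tibble::tibble(
    design_id = as.character(design_id),
    beta1_deg = as.numeric(beta1_deg),
    beta2_deg = as.numeric(beta2_deg),
    alpha2_deg = as.numeric(alpha2_deg),
    cl_imp_mm = as.numeric(cl_imp_mm),
    cl_diff_mm = as.numeric(cl_diff_mm)
  )
  check_designs(d)
  d
}

check_designs <- function(designs, require_beta_order = TRUE) {
  miss <- setdiff(c("design_id", DESIGN_PARAMS), names(designs))
  if (length(miss) > 0) {
    abort_validation(paste0("designs are missing columns: ",
                            paste(miss, collapse = ", ")))
  }
  ang <- c(designs$beta1_deg, designs$beta2_deg, designs$alpha2_deg)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang > 90)) {
    abort_validation("blade angles must lie in (0, 90] degrees")
  }
  ch <- c(designs$cl_imp_mm, designs$cl_diff_mm)
  if (any(!is.finite(ch)) || any(ch <= 0)) {
    abort_validation("chord lengths must be positive")
  }
  if (require_beta_order && any(designs$beta2_deg <= designs$beta1_deg)) {
    abort_validation("impeller outlet angle beta2 must exceed inlet angle beta1")
  }
  invisible(designs)
}

#' Circular-arc camber line at mid-span
#'
#' Builds the circular-arc camber line implied by an inlet blade angle, an
#' outlet blade angle and a chord length, in the unwrapped two-dimensional
#' blade-to-blade plane (x tangential, y axial). The arc radius follows from
#' the chord and the turning angle theta = outlet - inlet as
#' `R = chord / (2 sin(theta / 2))`; a zero turning angle degenerates to a
#' straight segment (infinite radius). The inlet endpoint sits at the origin
#' and the chord points along the stagger direction `(inlet + outlet) / 2`,
#' so the blade tangent rotates monotonically from the inlet to the outlet
#' angle along the arc.
#'
#' @param inlet_angle_deg,outlet_angle_deg Endpoint tangent angles in degrees
#'   from tangential, each in (0, 90].
#' @param chord_mm Chord length in mm (straight-line distance between the
#'   endpoints), positive.
#' @param n_points Number of sampled points along the camber line (>= 2).
#'
#' @return An object of class `camber_arc`: a list with `chord_mm`,
#'   `inlet_angle_deg`, `outlet_angle_deg`, `turning_angle_deg`,
#'   `arc_radius_mm` (`Inf` for a straight blade) and `points`, a tibble of
#'   `(x_mm, y_mm)` coordinates ordered from inlet to outlet.
#' @examples
#' arc <- camber_arc(25, 90, 9, n_points = 50)
#' arc$arc_radius_mm # 9 / (2 * sin(32.5 deg))
#' @export
camber_arc <- function(inlet_angle_deg, outlet_angle_deg, chord_mm,
                       n_points = 50) {
  if (!is.finite(chord_mm) || chord_mm <= 0) {
    abort_validation("chord_mm must be positive")
  }
  for (a in c(inlet_angle_deg, outlet_angle_deg)) {
    if (!is.finite(a) || a <= 0 || a > 90) {
      abort_validation("camber-arc angles must lie in (0, 90] degrees")
    }
  }
  if (n_points < 2) abort_validation("n_points must be at least 2")

  theta_deg <- outlet_angle_deg - inlet_angle_deg
  b_in <- inlet_angle_deg * pi / 180
  theta <- theta_deg * pi / 180

  if (abs(theta_deg) < 1e-12) {
    t <- seq(0, 1, length.out = n_points)
    pts <- tibble::tibble(
      x_mm = chord_mm * t * cos(b_in),
      y_mm = chord_mm * t * sin(b_in)
    )
    radius <- Inf
  } else {
    radius <- chord_mm / (2 * sin(abs(theta) / 2))
    # centre on the side that makes the tangent angle advance from inlet to
    # outlet; parametrise by tangent angle b_in + t, t in [0, theta]
    s <- sign(theta)
    cx <- -s * radius * sin(b_in)
    cy <- s * radius * cos(b_in)
    t <- seq(0, theta, length.out = n_points)
    pts <- tibble::tibble(
      x_mm = cx + s * radius * sin(b_in + t),
      y_mm = cy - s * radius * cos(b_in + t)
    )
    # anchor inlet exactly at the origin
    pts$x_mm <- pts$x_mm - pts$x_mm[1]
    pts$y_mm <- pts$y_mm - pts$y_mm[1]
  }
  structure(
    list(
      chord_mm = chord_mm,
      inlet_angle_deg = inlet_angle_deg,
      outlet_angle_deg = outlet_angle_deg,
      turning_angle_deg = theta_deg,
      arc_radius_mm = radius,
      points = pts
    ),
    class = "camber_arc"
  )
}

#' @export
print.camber_arc <- function(x, ...) {
  cat(sprintf(
    "<camber_arc> chord %.3f mm, %g -> %g deg (turning %g deg), R = %s mm, %d points\n",
    x$chord_mm, x$inlet_angle_deg, x$outlet_angle_deg, x$turning_angle_deg,
    ifelse(is.finite(x$arc_radius_mm), sprintf("%.4f", x$arc_radius_mm), "Inf"),
    nrow(x$points)
  ))
  invisible(x)
}

#' Two-level full-factorial blade designs
#'
#' Enumerates every combination of a low and a high value for each of the
#' five governing parameters: 2^5 = 32 designs when all five (low, high)
#' pairs are distinct. Ordering is deterministic lexicographic over
#' (beta1, beta2, alpha2, cl_imp, cl_diff) with low before high, so design
#' ids are stable across runs. Combinations violating the blade-orientation
#' constraint beta2 > beta1 are kept but flagged in a `feasible` column
#' (present only when violations occur) with a warning.
#'
#' @param low_high A named list with entries `beta1_deg`, `beta2_deg`,
#'   `alpha2_deg`, `cl_imp_mm`, `cl_diff_mm`, each a numeric `c(low, high)`
#'   with low <= high. Defaults to the extremes of [constraint_box()]
#'   iteration 0.
#'
#' @return A tibble of designs (see [blade_design()]); duplicated rows
#'   arising from a collapsed factor (low == high) are dropped.
#' @examples
#' nrow(factorial_designs()) # 32
#' @export
factorial_designs <- function(low_high = NULL) {
  if (is.null(low_high)) {
    box <- constraint_box(0)
    low_high <- stats::setNames(
      purrr::map2(box$min, box$max, c), box$parameter
    )
  }
  miss <- setdiff(DESIGN_PARAMS, names(low_high))
  if (length(miss) > 0) {
    abort_validation(paste0("low_high is missing: ", paste(miss, collapse = ", ")))
  }
  for (p in DESIGN_PARAMS) {
    lh <- low_high[[p]]
    if (length(lh) != 2 || any(!is.finite(lh)) || lh[1] > lh[2]) {
      abort_validation(sprintf("low_high$%s must be c(low, high) with low <= high", p))
    }
  }
  # expand.grid varies the first factor fastest: list cl_diff first so beta1
  # is the most significant digit of the lexicographic order
  grid <- expand.grid(
    cl_diff_mm = unique(low_high$cl_diff_mm),
    cl_imp_mm = unique(low_high$cl_imp_mm),
    alpha2_deg = unique(low_high$alpha2_deg),
    beta2_deg = unique(low_high$beta2_deg),
    beta1_deg = unique(low_high$beta1_deg),
    KEEP.OUT.ATTRS = FALSE
  )
  d <- tibble::as_tibble(grid)[, DESIGN_PARAMS]
  d <- dplyr::mutate(d, design_id = sprintf("d%02d", dplyr::row_number()),
                     .before = 1)
  check_designs(d, require_beta_order = FALSE)
  bad <- d$beta2_deg <= d$beta1_deg
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d factorial combination(s) violate beta2 > beta1; flagged in `feasible`",
      sum(bad)
    ))
    d$feasible <- !bad
  }
  d
}

#' Sequential boundary-constraint boxes
#'
#' Returns the parameter bounds for one constraint iteration of the
#' optimisation. Iteration 0 equals the extremes of the original 32-design
#' factorial (beta1 25-40, beta2 75-90, alpha2 25-40, chords 9-14 mm); each
#' further iteration widens the angle bounds by 5 degrees per side and the
#' chord bounds by 1 mm per side, with the beta2 upper bound capped at 90
#' degrees. Boxes are therefore nested: box k is contained in box k + 1.
#'
#' @param iteration_index Integer between 0 and 4.
#'
#' @return An object of class `constraint_box`: a tibble with columns
#'   `parameter`, `min`, `max` and attribute `iteration`.
#' @examples
#' constraint_box(0)
#' constraint_box(3)
#' @export
constraint_box <- function(iteration_index) {
  k <- iteration_index
  if (length(k) != 1 || !is.finite(k) || k != round(k) || k < 0 || k > 4) {
    abort_validation("iteration_index must be an integer between 0 and 4")
  }
  box <- tibble::tibble(
    parameter = DESIGN_PARAMS,
    min = c(25 - 5 * k, 75 - 5 * k, 25 - 5 * k, 9 - k, 9 - k),
    max = c(40 + 5 * k, 90, 40 + 5 * k, 14 + k, 14 + k)
  )
  structure(box, iteration = as.integer(k),
            class = c("constraint_box", class(tibble::tibble())))
}

box_bounds <- function(box) {
  stopifnot(inherits(box, "constraint_box"))
  list(lower = stats::setNames(box$min, box$parameter),
       upper = stats::setNames(box$max, box$parameter))
}

#' Check designs against a constraint box
#'
#' Reports, per design, whether the blade-orientation constraint
#' beta2 > beta1 holds and whether each parameter lies within the box
#' bounds. This is a report, not an exception: infeasible designs are simply
#' flagged.
#'
#' @param designs A designs tibble (see [blade_design()]); out-of-order
#'   beta angles are permitted here and reported.
#' @param box A [constraint_box()].
#'
#' @return A tibble with one row per design: `design_id`, `beta_order_ok`,
#'   one `<parameter>_ok` column per parameter, and overall `feasible`.
#' @examples
#' d <- blade_design(25, 90, 25, 9, 9)
#' validate_designs(d, constraint_box(0))$feasible
#' @export
validate_designs <- function(designs, box) {
  check_designs(designs, require_beta_order = FALSE)
  b <- box_bounds(box)
  rep <- tibble::tibble(
    design_id = designs$design_id,
    beta_order_ok = designs$beta2_deg > designs$beta1_deg
  )
  for (p in DESIGN_PARAMS) {
    rep[[paste0(p, "_ok")]] <-
      designs[[p]] >= b$lower[[p]] & designs[[p]] <= b$upper[[p]]
  }
  rep$feasible <- rep$beta_order_ok &
    purrr::reduce(rep[paste0(DESIGN_PARAMS, "_ok")], `&`)
  rep
}
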