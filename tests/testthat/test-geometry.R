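test_that("camber arc degenerates to a straight segment at zero turning", {
  arc <- camber_arc(30, 30, 10, n_points = 2)
  expect_identical(arc$arc_radius_mm, Inf)
  p <- arc$points
  expect_equal(sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2), 10, tolerance = 1e-12)
})

test_that("camber arc radius, chord and endpoint tangents match the closed form", {
  arc <- camber_arc(25, 90, 9, n_points = 51)
  expect_equal(arc$arc_radius_mm, 9 / (2 * sin(32.5 * pi / 180)),
               tolerance = 1e-12)
  p <- arc$points
  n <- nrow(p)
  chord <- sqrt((p$x_mm[n] - p$x_mm[1])^2 + (p$y_mm[n] - p$y_mm[1])^2)
  expect_equal(chord, 9, tolerance = 1e-9)
  # endpoint tangents by finite differencing the sampled points, within 0.1 deg
  tan_in <- atan2(p$y_mm[2] - p$y_mm[1], p$x_mm[2] - p$x_mm[1]) * 180 / pi
  tan_out <- atan2(p$y_mm[n] - p$y_mm[n - 1], p$x_mm[n] - p$x_mm[n - 1]) * 180 / pi
  # half the sampled-angle step separates the secant from the true tangent
  step <- arc$turning_angle_deg / (n - 1)
  expect_lt(abs(tan_in - (25 + step / 2)), 0.1)
  expect_lt(abs(tan_out - (90 - step / 2)), 0.1)
})

test_that("camber arc midpoint sagitta equals R (1 - cos(theta/2))", {
  arc <- camber_arc(25, 90, 9, n_points = 51)
  p <- arc$points
  n <- nrow(p)
  a <- c(p$x_mm[1], p$y_mm[1])
  b <- c(p$x_mm[n], p$y_mm[n])
  mid <- c(p$x_mm[(n + 1) / 2], p$y_mm[(n + 1) / 2])
  u <- (b - a) / sqrt(sum((b - a)^2))
  v <- mid - a
  sagitta <- abs(v[2] * u[1] - v[1] * u[2])
  theta <- arc$turning_angle_deg * pi / 180
  expect_equal(sagitta, arc$arc_radius_mm * (1 - cos(theta / 2)),
               tolerance = 1e-9)
})

test_that("reversed traversal mirrors the arc and preserves the chord", {
  fwd <- camber_arc(25, 90, 9, n_points = 21)
  rev <- camber_arc(90, 25, 9, n_points = 21)
  expect_equal(rev$arc_radius_mm, fwd$arc_radius_mm, tolerance = 1e-12)
  chord <- function(p) sqrt((p$x_mm[21] - p$x_mm[1])^2 +
                              (p$y_mm[21] - p$y_mm[1])^2)
  expect_equal(chord(rev$points), chord(fwd$points), tolerance = 1e-12)
})

test_that("camber arc rejects invalid inputs", {
  expect_error(camber_arc(25, 90, 0), class = "bladeforge_error_validation")
  expect_error(camber_arc(0, 90, 9), class = "bladeforge_error_validation")
  expect_error(camber_arc(25, 95, 9), class = "bladeforge_error_validation")
  expect_error(camber_arc(25, 90, 9, n_points = 1),
               class = "bladeforge_error_validation")
})

test_that("two-level factorial yields 32 designs, 8 impellers, 4 diffusers", {
  d <- factorial_designs()
  expect_equal(nrow(d), 32)
  expect_equal(nrow(dplyr::distinct(d, beta1_deg, beta2_deg, cl_imp_mm)), 8)
  expect_equal(nrow(dplyr::distinct(d, alpha2_deg, cl_diff_mm)), 4)
  # lexicographic over (beta1, beta2, alpha2, cl_imp, cl_diff), low first
  expect_equal(unlist(d[1, 2:6]), c(beta1_deg = 25, beta2_deg = 75,
                                    alpha2_deg = 25, cl_imp_mm = 9,
                                    cl_diff_mm = 9))
  expect_equal(d$cl_diff_mm[1:2], c(9, 14))
  expect_true(all(d$beta1_deg[1:16] == 25) && all(d$beta1_deg[17:32] == 40))
  expect_identical(d$design_id, sprintf("d%02d", 1:32))
})

test_that("collapsed factor halves the factorial and violations are flagged", {
  lh <- list(beta1_deg = c(25, 40), beta2_deg = c(75, 90),
             alpha2_deg = c(25, 40), cl_imp_mm = c(9, 14),
             cl_diff_mm = c(11, 11))
  expect_equal(nrow(factorial_designs(lh)), 16)

  lh <- list(beta1_deg = c(25, 80), # 80 > 75 violates beta2 > beta1 somewhere
             beta2_deg = c(75, 90), alpha2_deg = c(25, 40),
             cl_imp_mm = c(9, 14), cl_diff_mm = c(9, 14))
  expect_warning(d <- factorial_designs(lh), "beta2 > beta1")
  expect_true("feasible" %in% names(d))
  expect_equal(sum(!d$feasible), 8) # beta1 = 80 x beta2 = 75 combinations
  expect_equal(nrow(d), 32)         # flagged, not dropped
})

test_that("constraint boxes follow the tabulated widening and stay nested", {
  b0 <- constraint_box(0)
  expect_equal(b0$min, c(25, 75, 25, 9, 9))
  expect_equal(b0$max, c(40, 90, 40, 14, 14))
  b3 <- constraint_box(3)
  expect_equal(b3$min, c(10, 60, 10, 6, 6))
  expect_equal(b3$max, c(55, 90, 55, 17, 17))
  for (k in 0:3) {
    inner <- constraint_box(k)
    outer <- constraint_box(k + 1)
    expect_true(all(outer$min <= inner$min) && all(outer$max >= inner$max))
  }
  expect_error(constraint_box(5), class = "bladeforge_error_validation")
  expect_error(constraint_box(-1), class = "bladeforge_error_validation")
})

test_that("iteration-0 box equals the parameter-wise factorial extremes", {
  d <- factorial_designs()
  b0 <- constraint_box(0)
  for (j in seq_along(b0$parameter)) {
    expect_equal(min(d[[b0$parameter[j]]]), b0$min[j])
    expect_equal(max(d[[b0$parameter[j]]]), b0$max[j])
  }
  expect_true(all(validate_designs(d, b0)$feasible))
})

test_that("design feasibility reports bound and orientation violations", {
  expect_true(validate_designs(blade_design(25, 90, 25, 9, 9),
                               constraint_box(0))$feasible)

  rep <- validate_designs(
    tibble::tibble(design_id = "bad", beta1_deg = 40, beta2_deg = 35,
                   alpha2_deg = 25, cl_imp_mm = 9, cl_diff_mm = 9),
    constraint_box(0)
  )
  expect_false(rep$beta_order_ok)
  expect_false(rep$feasible)

  d <- tibble::tibble(design_id = "edge", beta1_deg = 9, beta2_deg = 90,
                      alpha2_deg = 25, cl_imp_mm = 9, cl_diff_mm = 9)
  expect_false(validate_designs(d, constraint_box(3))$feasible)
  expect_true(validate_designs(d, constraint_box(4))$feasible)
})
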