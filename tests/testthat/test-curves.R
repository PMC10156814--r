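quartic_samples <- function(coefs, q = seq(0.5, 4, by = 0.5)) {
  tibble::tibble(
    design_id = "syn", omega_rpm = 20000, q_lpm = q,
    dp_mmhg = coefs[1] * q^4 + coefs[2] * q^3 + coefs[3] * q^2 +
      coefs[4] * q + coefs[5],
    eta = seq(0.1, 0.3, length.out = length(q))
  )
}

test_that("quartic fitting recovers exact polynomial data and matches the
           normal-equations oracle", {
  coefs <- c(1, -2, 0, 3, 40)
  fit <- fit_quartic(quartic_samples(coefs))
  expect_no_mismatch(unname(fit$coefficients), coefs, 1e-8)
  expect_lt(fit$rmse_of_fit, 1e-9)
  expect_equal(fit$valid_range, c(0.5, 4))

  set.seed(11)
  for (i in 1:5) {
    crv <- quartic_samples(runif(5, -5, 5))
    crv$dp_mmhg <- crv$dp_mmhg + rnorm(8, sd = 2)
    fit <- fit_quartic(crv)
    oracle <- normal_equations_quartic(crv$q_lpm, crv$dp_mmhg)
    expect_no_mismatch(unname(fit$coefficients), oracle, 1e-7)
  }
})

test_that("constant-pressure samples collapse to the intercept", {
  crv <- quartic_samples(c(0, 0, 0, 0, 70))
  fit <- fit_quartic(crv)
  expect_no_mismatch(unname(fit$coefficients)[1:4], rep(0, 4), 1e-9)
  expect_equal(unname(fit$coefficients)[5], 70, tolerance = 1e-9)
})

test_that("quartic fitting rejects short or degenerate curves", {
  crv <- quartic_samples(c(1, -2, 0, 3, 40))
  expect_error(fit_quartic(crv[1:4, ]), class = "bladeforge_error_validation")
  dup <- crv
  dup$q_lpm[2] <- dup$q_lpm[1]
  expect_error(fit_quartic(dup), class = "bladeforge_error_validation")
})

test_that("flow and pressure coefficients are computed in SI units", {
  expect_equal(phi_psi(0, 70, 20000)$phi, 0)
  x <- phi_psi(2, 70, 20000)
  expect_equal(x$phi, 0.0349, tolerance = 2e-3)
  expect_equal(x$psi, 0.0342, tolerance = 2e-3)
})

test_that("a curve through the target matches at the target itself", {
  coefs <- c(0.2, -1, -2, 1, 0)
  coefs[5] <- 70 - sum(coefs[1:4] * c(16, 8, 4, 2)) # force dP(2) = 70
  fit <- fit_quartic(quartic_samples(coefs))
  m <- match_operating_point(fit, operating_point(2, 70))
  expect_equal(m$q2_lpm, 2, tolerance = 1e-9)
  expect_equal(m$dp2_mmhg, 70, tolerance = 1e-8)
  expect_false(m$extrapolated)
})

test_that("match point satisfies both the curve and the affinity parabola", {
  designs <- random_box_designs(10, seed = 3)
  op <- operating_point(2, 70)
  for (i in 1:10) {
    crv <- simulate_curve(designs[i, ], 20000)
    fit <- fit_quartic(crv)
    m <- match_operating_point(fit, op)
    # on-curve (quartic) and on-parabola simultaneously, to 1e-9 relative
    expect_equal(m$dp2_mmhg, unname(predict_quartic(fit, m$q2_lpm)),
                 tolerance = 1e-9)
    expect_equal(m$dp2_mmhg, op$dp_mmhg * (m$q2_lpm / op$q_lpm)^2,
                 tolerance = 1e-9)
    # bisection oracle on the same intersection
    g <- function(q) predict_quartic(fit, q) - op$dp_mmhg * (q / op$q_lpm)^2
    q_oracle <- bisect_root(g, 0.5, 4)
    expect_equal(m$q2_lpm, q_oracle, tolerance = 1e-9)
  }
})

test_that("a parabola with no crossing raises an informative error", {
  crv <- quartic_samples(c(0, 0, -1, 0, -1)) # dP = -1 - Q^2 < 0 everywhere
  fit <- fit_quartic(crv)
  expect_error(match_operating_point(fit, operating_point(1, 100)),
               class = "bladeforge_error_no_root")
})

test_that("multiple in-range intersections warn and pick the nearest", {
  # g(Q) = (Q-1)(Q-2)(Q-3)(Q-4) has four roots; build the curve so that
  # subtracting the target parabola yields exactly this polynomial
  t <- 20 # dP1 / Q1^2
  coefs <- c(1, -10, 35 + t, -50, 24)
  fit <- fit_quartic(quartic_samples(coefs, q = seq(0.5, 4.5, by = 0.5)))
  op <- operating_point(2.2, t * 2.2^2)
  expect_warning(m <- match_operating_point(fit, op), "multiple")
  expect_equal(m$q2_lpm, 2, tolerance = 1e-7)
})

test_that("affinity speed scaling is exact ratio arithmetic", {
  expect_equal(scaled_speed(20000, 2, 2), 20000)
  expect_equal(scaled_speed(20000, 2, 2.5), 16000)
})

test_that("rescaling obeys the affinity laws and round-trips", {
  crv <- simulate_curve(mid_design(), 20000)
  expect_equal(rescale_curve(crv, 20000), crv)
  dbl <- rescale_curve(crv, 40000)
  expect_no_mismatch(dbl$dp_mmhg / crv$dp_mmhg, rep(4, 8), 1e-12)
  expect_no_mismatch(dbl$q_lpm / crv$q_lpm, rep(2, 8), 1e-12)

  # rescaled curve equals a fresh simulation at the new speed (oracle)
  down <- rescale_curve(crv, 15000)
  fresh <- simulate_curve(mid_design(), 15000, flow_lpm = down$q_lpm)
  expect_no_mismatch(down$dp_mmhg, fresh$dp_mmhg, 1e-9)
  expect_no_mismatch(down$eta, fresh$eta, 1e-12)

  # round-trip through a scaling and back reproduces the source
  sc <- scale_curve_to_op(crv, operating_point(2, 70))
  back <- rescale_curve(sc$curve, 20000)
  expect_no_mismatch(back$dp_mmhg, crv$dp_mmhg, 1e-9)
  expect_no_mismatch(back$q_lpm, crv$q_lpm, 1e-9)
})

test_that("efficiency interpolation is linear, exact at samples and bounded", {
  crv <- tibble::tibble(design_id = "z", omega_rpm = 1000,
                        q_lpm = c(1.5, 2.5), dp_mmhg = c(50, 40),
                        eta = c(0.2, 0.3))
  expect_equal(efficiency_at(crv, 1.5), 0.2)
  expect_equal(efficiency_at(crv, 2.0), 0.25)
  expect_error(efficiency_at(crv, 1.0),
               class = "bladeforge_error_extrapolation")
})

test_that("curve RMSE matches the brute-force formula", {
  a <- simulate_curve(mid_design(), 20000)
  expect_equal(curve_rmse(a, a, "dp_mmhg"), 0)
  b <- dplyr::mutate(a, dp_mmhg = dp_mmhg + 3)
  expect_equal(curve_rmse(a, b, "dp_mmhg"), 3, tolerance = 1e-12)

  set.seed(5)
  pert <- dplyr::mutate(a, dp_mmhg = dp_mmhg + rnorm(8))
  expect_equal(curve_rmse(a, pert, "dp_mmhg"),
               sqrt(mean((a$dp_mmhg - pert$dp_mmhg)^2)), tolerance = 1e-12)

  far <- dplyr::mutate(a, q_lpm = q_lpm + 100)
  expect_error(curve_rmse(a, far), class = "bladeforge_error_validation")
})

test_that("specific speed reproduces the published design value and scales", {
  ns <- specific_speed(15000, operating_point(2, 70))
  expect_equal(round(ns, 3), 1.762)
  # affinity scaling of the operating point leaves N_s unchanged
  k <- 1.4
  ns2 <- specific_speed(15000 * k, operating_point(2 * k, 70 * k^2))
  expect_equal(ns2, ns, tolerance = 1e-12)
  # sqrt(Q) dependence
  ns4 <- specific_speed(15000, operating_point(8, 70))
  expect_equal(ns4 / ns, 2, tolerance = 1e-12)
})

test_that("rotational Reynolds number matches the published estimate", {
  expect_equal(round(reynolds_rotational(20000), -3), 37000)
  expect_equal(reynolds_rotational(0), 0)
  big <- pump_constants(shroud_radius_mm = 7.7)
  expect_equal(reynolds_rotational(20000, big) / reynolds_rotational(20000),
               4, tolerance = 1e-12)
})
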