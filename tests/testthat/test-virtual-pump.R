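test_that("impeller incidence vanishes at the zero-incidence flow", {
  d <- mid_design()
  cst <- pump_constants()
  # cx * cot(beta1) = U  <=>  Q* = U * A * tan(beta1)
  u <- 20000 * pi / 30 * (cst$hub_radius_mm + cst$shroud_radius_mm) / 2 * 1e-3
  area <- pi * ((cst$shroud_radius_mm * 1e-3)^2 - (cst$hub_radius_mm * 1e-3)^2)
  q_star <- u * area * tan(32.5 * pi / 180) * 60000
  with_inc <- simulate_curve(d, 20000, flow_lpm = q_star)
  no_inc <- simulate_curve(d, 20000, flow_lpm = q_star,
                           losses = loss_coefficients(k_inc = 0))
  expect_equal(with_inc$dp_mmhg, no_inc$dp_mmhg, tolerance = 1e-12)
})

test_that("the model is exactly affinity-invariant", {
  d <- random_box_designs(5, seed = 42)
  q <- seq(0.5, 4, by = 0.5)
  k <- 1.3
  for (i in 1:5) {
    base <- simulate_curve(d[i, ], 20000, q)
    scaled <- simulate_curve(d[i, ], 20000 * k, q * k)
    expect_no_mismatch(scaled$eta, base$eta, 1e-12)
    expect_no_mismatch(scaled$dp_mmhg / base$dp_mmhg, rep(k^2, length(q)),
                       1e-12)
  }
})

test_that("every governing parameter moves the design-point efficiency", {
  base <- mid_design()
  op <- operating_point(2, 70)
  eta_at_target <- function(dsn) {
    crv <- simulate_curve(dsn, 20000)
    efficiency_at(scale_curve_to_op(crv, op)$curve, 2)
  }
  eta0 <- eta_at_target(base)
  for (p in c("beta1_deg", "beta2_deg", "alpha2_deg", "cl_imp_mm",
              "cl_diff_mm")) {
    pert <- base
    pert[[p]] <- pert[[p]] + 1
    expect_gt(abs(eta_at_target(pert) - eta0), 1e-8)
  }
})

test_that("default coefficients give physiologically plausible magnitudes", {
  crv <- simulate_curve(mid_design(), 20000)
  in_band <- crv$q_lpm >= 0.5 & crv$q_lpm <= 2
  expect_true(all(crv$dp_mmhg[in_band] > 50 & crv$dp_mmhg[in_band] < 150))
  # best factorial design lands between 0.1 and 0.5 at the scaled design point
  bl <- cached_baseline()
  expect_gt(bl$baseline$eta_at_op, 0.1)
  expect_lt(bl$baseline$eta_at_op, 0.5)
})

test_that("pressure noise is seed-gated, reproducible and confined to dP", {
  d <- mid_design()
  expect_error(simulate_curve(d, 20000, noise_sd = 1),
               class = "bladeforge_error_validation")
  a <- simulate_curve(d, 20000, noise_sd = 1, seed = 7)
  b <- simulate_curve(d, 20000, noise_sd = 1, seed = 7)
  clean <- simulate_curve(d, 20000)
  expect_identical(a$dp_mmhg, b$dp_mmhg)
  expect_false(all(a$dp_mmhg == clean$dp_mmhg))
  expect_identical(a$eta, clean$eta)
})

test_that("simulation requests are validated", {
  d <- mid_design()
  expect_error(simulate_curve(d, 0), class = "bladeforge_error_validation")
  expect_error(simulate_curve(d, 20000, flow_lpm = c(2, 1)),
               class = "bladeforge_error_validation")
  expect_error(simulate_curve(d, 20000, flow_lpm = c(-1, 2)),
               class = "bladeforge_error_validation")
  two <- factorial_designs()[1:2, ]
  expect_error(simulate_curve(two, 20000),
               class = "bladeforge_error_validation")
})
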