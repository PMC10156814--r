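linearised_dataset <- function(noise_sd = 0, seed = 9) {
  # virtual-pump dataset with targets replaced by a known linear map
  ds <- cached_baseline()$dataset
  set.seed(seed)
  ds$eta_at_op <- 0.3 + 0.004 * ds$beta1_deg - 0.002 * ds$beta2_deg +
    0.001 * ds$alpha2_deg - 0.003 * ds$cl_imp_mm + 0.002 * ds$cl_diff_mm +
    rnorm(nrow(ds), sd = noise_sd)
  attr(ds, "normalisation")$target <-
    c(min = min(ds$eta_at_op), max = max(ds$eta_at_op))
  ds
}

test_that("dataset pairs 32 designs with design-point efficiencies and an
           invertible [-1, 1] normalisation", {
  bl <- cached_baseline()
  ds <- bl$dataset
  expect_equal(nrow(ds), 32)
  expect_s3_class(ds, "design_dataset")
  xn <- bladeforge:::normalise_features(ds, attr(ds, "normalisation"))
  expect_true(all(xn >= -1 - 1e-12 & xn <= 1 + 1e-12))
  yn <- bladeforge:::normalise_target(ds$eta_at_op, attr(ds, "normalisation"))
  expect_true(all(abs(yn) <= 1 + 1e-12))
  back <- bladeforge:::denormalise_target(yn, attr(ds, "normalisation"))
  expect_no_mismatch(back, ds$eta_at_op, 1e-12)
})

test_that("designs whose scaled curve misses the target flow are excluded
           with a warning", {
  bl <- cached_baseline()
  crippled <- dplyr::filter(bl$scaled_curves,
                            !(design_id == "d01" & q_lpm < 2.5))
  expect_warning(
    ds <- build_design_dataset(bl$designs, crippled, operating_point(2, 70)),
    "d01"
  )
  expect_equal(nrow(ds), 31)
  expect_identical(attr(ds, "excluded"), "d01")
})

test_that("degenerate constant targets map to zero under the zero-span rule", {
  bl <- cached_baseline()
  ds <- bl$dataset
  ds$eta_at_op <- rep(0.25, nrow(ds))
  attr(ds, "normalisation")$target <- c(min = 0.25, max = 0.25)
  yn <- bladeforge:::normalise_target(ds$eta_at_op, attr(ds, "normalisation"))
  expect_true(all(yn == 0))
  m <- fit_mlr(ds)
  expect_lt(m$metrics$rmse_all, 1e-12)
})

test_that("multi-linear regression recovers exact linear targets and matches
           a hand-computed prediction", {
  ds <- linearised_dataset(noise_sd = 0)
  m <- fit_mlr(ds)
  expect_lt(m$metrics$rmse_all, 1e-10)
  expect_length(m$coefficients, 6)

  new <- blade_design(30, 85, 30, 10, 12, design_id = "probe")
  xn <- bladeforge:::normalise_features(new, m$normalisation)
  by_hand <- unname(bladeforge:::denormalise_target(
    m$coefficients[1] + sum(m$coefficients[-1] * xn[1, ]), m$normalisation
  ))
  expect_equal(predict(m, new), by_hand, tolerance = 1e-12)
  expect_error(fit_mlr(ds[1:6, ]), class = "bladeforge_error_validation")
})

test_that("noise-free GPR interpolates its training data", {
  bl <- cached_baseline()
  m <- fit_gpr(bl$dataset, seed = 2)
  expect_no_mismatch(predict(m, bl$dataset), bl$dataset$eta_at_op, 1e-6)
})

test_that("GPR beats a nearest-neighbour baseline inside the design box", {
  ds <- cached_baseline()$dataset
  m <- fit_gpr(ds, seed = 2)
  expect_lt(m$metrics$rmse_all, m$metrics$rmse_validation + 1e-12)

  interior <- random_box_designs(20, seed = 8)
  truth <- purrr::map_dbl(seq_len(20), function(i) {
    crv <- simulate_curve(interior[i, ], 20000)
    efficiency_at(scale_curve_to_op(crv, operating_point(2, 70))$curve, 2)
  })
  gpr_err <- sqrt(mean((predict(m, interior) - truth)^2))
  xn_tr <- bladeforge:::normalise_features(ds, attr(ds, "normalisation"))
  xn_new <- bladeforge:::normalise_features(interior, attr(ds, "normalisation"))
  nn_err <- sqrt(mean((nn_predict(xn_tr, ds$eta_at_op, xn_new) - truth)^2))
  expect_lt(gpr_err, nn_err)
})

test_that("the four-kernel comparison reports a ranking", {
  ds <- cached_baseline()$dataset
  cmp <- compare_gpr_kernels(ds, seed = 2)
  expect_equal(nrow(cmp), 4)
  expect_setequal(cmp$kernel,
                  c("matern52", "sqexp", "exp", "rationalquadratic"))
  expect_false(is.unsorted(cmp$rmse_validation))
})

test_that("BRANN holds out 5 of 32 designs and is seed-reproducible", {
  ds <- cached_baseline()$dataset
  m1 <- fit_brann(ds, seed = 3)
  m2 <- fit_brann(ds, seed = 3)
  expect_length(m1$holdout, 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$metrics, m2$metrics)
  m3 <- suppressWarnings(fit_brann(ds, seed = 4))
  expect_false(identical(m1$holdout, m3$holdout) &&
                 identical(m1$weights, m3$weights))
})

test_that("BRANN fits near-linear targets tightly with spare capacity", {
  ds <- linearised_dataset(noise_sd = 0.002)
  m <- fit_brann(ds, seed = 5)
  expect_lt(m$metrics$rmse_train, 0.005)
  expect_lt(m$gamma, length(m$weights)) # evidence leaves weights unused
})

test_that("stronger weight decay shrinks the BRANN weight norm", {
  ds <- linearised_dataset(noise_sd = 0.002)
  norm <- attr(ds, "normalisation")
  x <- bladeforge:::normalise_features(ds, norm)
  y <- bladeforge:::normalise_target(ds$eta_at_op, norm)
  f_small <- bladeforge:::brann_train(x, y, 5, seed = 2, evidence = FALSE,
                                      alpha0 = 0.01, beta0 = 1)
  f_big <- bladeforge:::brann_train(x, y, 5, seed = 2, evidence = FALSE,
                                    alpha0 = 10, beta0 = 1)
  expect_lt(sum(f_big$weights^2), sum(f_small$weights^2))
})

test_that("surrogate predictions flag extrapolation outside the training box", {
  ds <- cached_baseline()$dataset
  m <- fit_mlr(ds)
  inside <- blade_design(30, 85, 30, 10, 12, design_id = "in")
  outside <- blade_design(10, 90, 10, 6, 6, design_id = "out")
  expect_false(predict_design_eta(m, inside)$extrapolating)
  expect_true(predict_design_eta(m, outside)$extrapolating)
})

test_that("tidiers summarise surrogates, fits and scalings", {
  bl <- cached_baseline()
  ds <- bl$dataset
  expect_named(tidy(fit_mlr(ds)), c("term", "estimate"))
  g <- glance(fit_mlr(ds))
  expect_equal(g$kind, "MLR")
  fit <- fit_quartic(dplyr::filter(bl$curves, design_id == "d01"))
  expect_equal(nrow(tidy(fit)), 5)
  expect_named(glance(fit),
               c("rmse_of_fit_mmhg", "q_min_lpm", "q_max_lpm", "n"))
  sc <- scale_curve_to_op(dplyr::filter(bl$curves, design_id == "d01"),
                          operating_point(2, 70))
  expect_equal(glance(sc)$omega_scaled_rpm, sc$omega_scaled_rpm)
  expect_s3_class(tidy(sc), "tbl_df")
})
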