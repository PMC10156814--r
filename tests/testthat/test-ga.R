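sphere_objective <- function(centre) {
  function(d) {
    (d$beta1_deg - centre[1])^2 + (d$beta2_deg - centre[2])^2 +
      (d$alpha2_deg - centre[3])^2 + (d$cl_imp_mm - centre[4])^2 +
      (d$cl_diff_mm - centre[5])^2
  }
}

test_that("the GA finds an interior optimum of a separable convex objective", {
  centre <- c(30, 80, 30, 11, 11)
  res <- ga_optimize(sphere_objective(centre), constraint_box(0),
                     ga_config(seed = 1))
  box <- constraint_box(0)
  sol <- unlist(res$best_design[, box$parameter])
  expect_true(all(abs(sol - centre) / (box$max - box$min) <= 1e-2))
  expect_true(res$feasibility$feasible)
})

test_that("every evaluated candidate respects the box and blade orientation", {
  box <- constraint_box(1)
  b <- bladeforge:::box_bounds(box)
  seen_violation <- FALSE
  spy <- function(d) {
    ok <- d$beta2_deg > d$beta1_deg
    for (p in names(b$lower)) {
      ok <- ok & d[[p]] >= b$lower[[p]] - 1e-12 & d[[p]] <= b$upper[[p]] + 1e-12
    }
    if (!all(ok)) seen_violation <<- TRUE
    (d$beta1_deg - 20)^2 + (d$beta2_deg - 80)^2
  }
  res <- ga_optimize(spy, box, ga_config(max_generations = 80, seed = 2))
  expect_false(seen_violation)
  expect_true(res$feasibility$feasible)
})

test_that("elitism makes the best-fitness history non-increasing", {
  res <- ga_optimize(sphere_objective(c(30, 80, 30, 11, 11)),
                     constraint_box(0), ga_config(seed = 3))
  expect_true(all(diff(res$history$best_fitness) <= 0))
})

test_that("identical seed, config and objective give identical results", {
  obj <- sphere_objective(c(28, 85, 35, 10, 13))
  a <- ga_optimize(obj, constraint_box(0), ga_config(seed = 7))
  b <- ga_optimize(obj, constraint_box(0), ga_config(seed = 7))
  expect_identical(a$best_design, b$best_design)
  expect_identical(a$history, b$history)
  expect_identical(a$best_fitness, b$best_fitness)
})

test_that("an infeasible box is rejected", {
  box <- constraint_box(0)
  box$min[1] <- 92 # beta1 can never sit below beta2 <= 90
  box$max[1] <- 95
  expect_error(ga_optimize(sphere_objective(rep(1, 5)), box, ga_config()),
               class = "bladeforge_error_validation")
})

test_that("GA matches a brute-force grid on a smooth objective", {
  obj <- function(d) {
    -(sin(d$beta1_deg / 8) + cos(d$beta2_deg / 11) +
        sin(d$alpha2_deg / 7) * cos(d$cl_imp_mm / 3) + d$cl_diff_mm / 20)
  }
  box <- constraint_box(0)
  grid <- do.call(tidyr::expand_grid, purrr::map(
    stats::setNames(seq_len(5), box$parameter),
    ~ seq(box$min[.x], box$max[.x], length.out = 5)
  ))
  grid <- dplyr::mutate(grid, design_id = sprintf("g%04d", dplyr::row_number()),
                        .before = 1)
  grid_best <- min(obj(grid))
  res <- ga_optimize(obj, box, ga_config(seed = 5))
  expect_lte(res$best_fitness, grid_best + 1e-6)
})

test_that("repeatability reporting distinguishes sharp, spread and flat
           objectives", {
  sharp <- ga_repeatability(sphere_objective(c(30, 80, 30, 11, 11)),
                            constraint_box(0),
                            ga_config(max_generations = 120, seed = 1),
                            n_repeats = 3)
  expect_lt(sharp$max_spread_pct, 1)
  expect_true(sharp$within_tolerance)
  expect_false(sharp$non_identifiable)

  flat <- ga_repeatability(function(d) rep(1, nrow(d)), constraint_box(0),
                           ga_config(max_generations = 5, seed = 1),
                           n_repeats = 3)
  expect_true(flat$non_identifiable)
  expect_false(flat$within_tolerance)

  expect_error(ga_repeatability(sphere_objective(rep(1, 5)),
                                constraint_box(0), n_repeats = 1),
               class = "bladeforge_error_validation")
})
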