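#' Pipeline configuration
#'
#' Collects every setting of the end-to-end workflow: the target operating
#' point and the alternate (retargeting) points, the fixed simulation speed
#' and flow grid, the constraint iterations and surrogates to run, the GA
#' configuration, the analytic pump's loss coefficients and constants, and a
#' master seed from which every stage derives its own seed.
#'
#' @param target_op Target [operating_point()] (default 2 L/min @ 70 mmHg).
#' @param alternate_ops List of alternate operating points (defaults
#'   1 L/min @ 60 mmHg and 0.5 L/min @ 50 mmHg).
#' @param simulation_speed_rpm Speed at which all training curves are
#'   simulated (default 20,000 rpm).
#' @param flow_lpm Flow grid in L/min (default 0.5 to 4 by 0.5).
#' @param constraint_iterations Integer vector of iteration indices to run.
#' @param surrogates Character subset of `c("mlr", "gpr", "brann")`.
#' @param ga A [ga_config()] (its seed is overridden per stage).
#' @param constants,losses Pump constants and loss coefficients.
#' @param seed Master integer seed.
#' @return An object of class `pipeline_config`.
#' @examples
#' pipeline_config(seed = 1)
#' @export
pipeline_config <- function(target_op = operating_point(2, 70),
                            alternate_ops = list(operating_point(1, 60),
                                                 operating_point(0.5, 50)),
                            simulation_speed_rpm = 20000,
                            flow_lpm = seq(0.5, 4, by = 0.5),
                            constraint_iterations = 0:4,
                            surrogates = c("mlr", "gpr", "brann"),
                            ga = ga_config(),
                            constants = pump_constants(),
                            losses = loss_coefficients(),
                            seed = 1) {
  surrogates <- match.arg(surrogates, c("mlr", "gpr", "brann"),
                          several.ok = TRUE)
  for (op in c(list(target_op), alternate_ops)) {
    stopifnot(inherits(op, "operating_point"))
    if (op$q_lpm < min(flow_lpm) || op$q_lpm > max(flow_lpm)) {
      abort_validation(sprintf("flow grid does not cover %s", op$label))
    }
  }
  structure(
    list(target_op = target_op, alternate_ops = alternate_ops,
         simulation_speed_rpm = simulation_speed_rpm, flow_lpm = flow_lpm,
         constraint_iterations = constraint_iterations,
         surrogates = surrogates, ga = ga, constants = constants,
         losses = losses, seed = seed),
    class = "pipeline_config"
  )
}

# deterministic per-stage seed derivation from the master seed
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset) %% 2147483647)
}

#' Baseline stage: factorial designs, virtual curves, scaling, dataset
#'
#' Simulates the 32 two-level factorial designs on the flow grid at the
#' fixed simulation speed, scales each curve through the target operating
#' point, builds the surrogate dataset of design-point efficiencies, and
#' identifies the baseline (best factorial) design. Designs whose curves
#' cannot be scaled through the target are excluded with a logged reason;
#' the stage aborts if fewer than 20 designs survive.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pump_baseline`: a list with `designs`,
#'   `curves` (at simulation speed), `scaled_curves` (long tibble, each
#'   design at its scaled speed), `scalings` (per-design scaling summary),
#'   `dataset` (a [build_design_dataset()]), `baseline` (best row of the
#'   dataset) and `failed` (tibble of excluded designs and reasons).
#' @examples
#' \donttest{
#' bl <- run_baseline(pipeline_config(seed = 1))
#' bl$baseline
#' }
#' @export
run_baseline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  designs <- factorial_designs()
  curves <- simulate_curves(designs, config$simulation_speed_rpm,
                            config$flow_lpm, config$constants, config$losses)
  scaled <- purrr::map(designs$design_id, function(id) {
    crv <- dplyr::filter(curves, .data$design_id == id)
    tryCatch(scale_curve_to_op(crv, config$target_op),
             error = function(e) e)
  })
  names(scaled) <- designs$design_id
  ok <- !purrr::map_lgl(scaled, inherits, "error")
  failed <- tibble::tibble(
    design_id = designs$design_id[!ok],
    reason = purrr::map_chr(scaled[!ok], conditionMessage)
  )
  if (nrow(failed) > 0) {
    rlang::warn(sprintf("scaling failed for %d design(s): %s",
                        nrow(failed), paste(failed$design_id, collapse = ", ")))
  }
  if (sum(ok) < 20) {
    rlang::abort(sprintf(
      "only %d of %d designs could be scaled through %s; aborting",
      sum(ok), nrow(designs), config$target_op$label
    ), class = "bladeforge_error_pipeline")
  }
  scaled_curves <- dplyr::bind_rows(purrr::map(scaled[ok], "curve"))
  scalings <- tibble::tibble(
    design_id = designs$design_id[ok],
    omega_scaled_rpm = purrr::map_dbl(scaled[ok], "omega_scaled_rpm"),
    q2_lpm = purrr::map_dbl(scaled[ok], "q2_lpm"),
    dp2_mmhg = purrr::map_dbl(scaled[ok], "dp2_mmhg"),
    extrapolated = purrr::map_lgl(scaled[ok], "extrapolated")
  )
  dataset <- build_design_dataset(designs[ok, ], scaled_curves,
                                  config$target_op)
  baseline <- dataset[which.max(dataset$eta_at_op), ]
  structure(
    list(designs = designs, curves = curves, scaled_curves = scaled_curves,
         scalings = scalings, dataset = dataset, baseline = baseline,
         failed = failed, config = config),
    class = "pump_baseline"
  )
}

#' @export
print.pump_baseline <- function(x, ...) {
  cat(sprintf("<pump_baseline> %d designs scaled through %s; best: %s (eta = %.4f)\n",
              nrow(x$dataset), x$config$target_op$label,
              x$baseline$design_id, x$baseline$eta_at_op))
  invisible(x)
}

fit_surrogate <- function(kind, dataset, config) {
  switch(kind,
         mlr = fit_mlr(dataset),
         gpr = fit_gpr(dataset, kernel = "matern52", n_folds = 5,
                       seed = derive_seed(config$seed, 11)),
         brann = fit_brann(dataset, n_hidden = 5, holdout_fraction = 0.15,
                           seed = derive_seed(config$seed, 13)),
         abort_validation(sprintf("unknown surrogate '%s'", kind)))
}

#' Optimisation stage for one surrogate and constraint iteration
#'
#' Trains the requested surrogate on the baseline dataset, minimises its
#' negated prediction with the GA under the given constraint box, then
#' verifies the returned optimum by a fresh analytic-pump simulation scaled
#' to the target: the verified efficiency always comes from simulation,
#' never from the surrogate. The relative prediction error uses the
#' simulated value as denominator.
#'
#' @param config A [pipeline_config()].
#' @param baseline A [run_baseline()] result.
#' @param surrogate One of `"mlr"`, `"gpr"`, `"brann"`.
#' @param iteration_index Constraint-box iteration, 0 to 4.
#' @param run_repeats If `TRUE`, also run a 5-seed [ga_repeatability()]
#'   study.
#' @return An object of class `optimisation_result`: a list with `row` (a
#'   one-row summary tibble), the fitted `model`, the `ga` result, the
#'   verification `scaling` and optional `repeatability`.
#' @examples
#' \donttest{
#' bl <- run_baseline(pipeline_config(seed = 1))
#' run_optimisation(bl$config, bl, "mlr", 0)$row
#' }
#' @export
run_optimisation <- function(config, baseline, surrogate, iteration_index,
                             run_repeats = FALSE) {
  stopifnot(inherits(baseline, "pump_baseline"))
  model <- fit_surrogate(surrogate, baseline$dataset, config)
  box <- constraint_box(iteration_index)
  cfg <- config$ga
  cfg$seed <- derive_seed(config$seed, 100 + 10 * iteration_index +
                            match(surrogate, c("mlr", "gpr", "brann")))
  ga <- ga_optimize(surrogate_objective(model), box, cfg)
  predicted_eta <- -ga$best_fitness

  verify_curve <- simulate_curve(ga$best_design, config$simulation_speed_rpm,
                                 config$flow_lpm, config$constants,
                                 config$losses)
  scaling <- scale_curve_to_op(verify_curve, config$target_op)
  simulated_eta <- efficiency_at(scaling$curve, config$target_op$q_lpm)
  repeatability <- NULL
  if (run_repeats) {
    repeatability <- ga_repeatability(surrogate_objective(model), box, cfg,
                                      n_repeats = 5)
  }
  row <- dplyr::bind_cols(
    tibble::tibble(
      surrogate = toupper(surrogate),
      iteration = as.integer(iteration_index),
      predicted_eta = predicted_eta,
      simulated_eta = simulated_eta,
      rel_error_pct = 100 * abs(predicted_eta - simulated_eta) / simulated_eta,
      omega_scaled_rpm = scaling$omega_scaled_rpm,
      baseline_eta = baseline$baseline$eta_at_op,
      gain_pp = 100 * (simulated_eta - baseline$baseline$eta_at_op),
      gain_rel_pct = 100 * (simulated_eta - baseline$baseline$eta_at_op) /
        baseline$baseline$eta_at_op,
      generations = ga$generations,
      converged = ga$converged
    ),
    ga$best_design[, DESIGN_PARAMS]
  )
  structure(
    list(row = row, model = model, ga = ga, scaling = scaling,
         curve = verify_curve, repeatability = repeatability),
    class = "optimisation_result"
  )
}

#' @export
print.optimisation_result <- function(x, ...) {
  print(x$row)
  invisible(x)
}

#' Retarget a design to another operating point by rescaling alone
#'
#' Rescales an existing simulated curve through an alternate operating point
#' and interpolates the efficiency there. No new simulation is performed:
#' the affinity laws make the existing curve sufficient, so evaluating the
#' optimised design across the paediatric operating range costs nothing.
#'
#' @param curve The design's performance curve at the original simulation
#'   speed.
#' @param alternate_op An [operating_point()].
#' @return A one-row tibble: `label`, `q_lpm`, `dp_mmhg`,
#'   `omega_scaled_rpm`, `eta`, `extrapolated`.
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' retarget(crv, operating_point(1, 60))
#' @export
retarget <- function(curve, alternate_op) {
  sc <- scale_curve_to_op(curve, alternate_op)
  tibble::tibble(
    label = alternate_op$label,
    q_lpm = alternate_op$q_lpm,
    dp_mmhg = alternate_op$dp_mmhg,
    omega_scaled_rpm = sc$omega_scaled_rpm,
    eta = efficiency_at(sc$curve, alternate_op$q_lpm),
    extrapolated = sc$extrapolated
  )
}

#' Run the full inverse-design pipeline
#'
#' Orchestrates the workflow end to end: baseline (factorial designs,
#' simulation, scaling, dataset), one optimisation per requested surrogate
#' and constraint iteration (failures are recorded as failed rows and the
#' pipeline continues), selection of the best verified design, and
#' retargeting of that design to the alternate operating points.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given it must be writable
#'   (checked before any computation) and [write_report()] is called on the
#'   result.
#' @return An object of class `pipeline_report`: a list with `baseline`,
#'   `results` (summary tibble, one row per surrogate x iteration, with a
#'   `status` column), `optimisations` (the full result objects), `best`
#'   (the row with the highest verified efficiency), `retargeted` and
#'   `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(constraint_iterations = 0,
#'                                     surrogates = "mlr", seed = 1))
#' rep$results
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    probe <- file.path(outdir, ".write_probe")
    ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
                   warning = function(e) FALSE)
    if (!ok) {
      rlang::abort(sprintf("output directory '%s' is not writable", outdir),
                   class = "bladeforge_error_pipeline")
    }
    unlink(probe)
  }
  baseline <- run_baseline(config)
  grid <- tidyr::expand_grid(surrogate = config$surrogates,
                             iteration = config$constraint_iterations)
  opts <- purrr::pmap(grid, function(surrogate, iteration) {
    tryCatch(run_optimisation(config, baseline, surrogate, iteration),
             error = function(e) e)
  })
  ok <- !purrr::map_lgl(opts, inherits, "error")
  rows <- purrr::map2_dfr(opts, ok, function(o, is_ok) {
    if (is_ok) dplyr::mutate(o$row, status = "ok")
    else tibble::tibble(status = "failed")
  })
  if (any(!ok)) {
    if (!"surrogate" %in% names(rows)) rows$surrogate <- NA_character_
    if (!"iteration" %in% names(rows)) rows$iteration <- NA_integer_
    rows$surrogate[!ok] <- toupper(grid$surrogate[!ok])
    rows$iteration[!ok] <- as.integer(grid$iteration[!ok])
    rows$reason <- NA_character_
    rows$reason[!ok] <- purrr::map_chr(opts[!ok], conditionMessage)
  }
  best <- NULL
  retargeted <- NULL
  if (any(ok)) {
    sim_eta <- ifelse(rows$status == "ok", rows$simulated_eta, -Inf)
    best_i <- which.max(sim_eta)
    best <- rows[best_i, ]
    best_curve <- opts[[best_i]]$curve
    retargeted <- dplyr::bind_rows(
      retarget(best_curve, config$target_op),
      purrr::map_dfr(config$alternate_ops, ~ retarget(best_curve, .x))
    )
  }
  report <- structure(
    list(baseline = baseline, results = rows, optimisations = opts,
         best = best, retargeted = retargeted, config = config),
    class = "pipeline_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d surrogate x iteration combinations; baseline eta %.4f\n",
              nrow(x$results), x$baseline$baseline$eta_at_op))
  print(dplyr::select(x$results, dplyr::any_of(c(
    "surrogate", "iteration", "predicted_eta", "simulated_eta",
    "rel_error_pct", "status"
  ))))
  invisible(x)
}
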