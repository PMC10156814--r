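#' Read and write blade designs
#'
#' Designs travel as CSV with header
#' `design_id,beta1_deg,beta2_deg,alpha2_deg,cl_imp_mm,cl_diff_mm` or as
#' JSON arrays of objects with the same keys.
#'
#' @param designs A designs tibble.
#' @param path File path (`.csv` or `.json`).
#' @return `write_designs()` returns `path` invisibly; `read_designs()`
#'   returns a validated designs tibble.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_designs(factorial_designs(), p)
#' nrow(read_designs(p))
#' @export
write_designs <- function(designs, path) {
  check_designs(designs, require_beta_order = FALSE)
  d <- designs[, c("design_id", DESIGN_PARAMS)]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, auto_unbox = FALSE, digits = NA)
  } else {
    readr::write_csv(d, path)
  }
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  check_designs(d, require_beta_order = FALSE)
  d[, c("design_id", DESIGN_PARAMS)]
}

#' Read and write performance curves
#'
#' Curve samples travel as CSV with header
#' `design_id,omega_rpm,q_lpm,dp_mmhg,eta`, one row per sampled flow rate.
#'
#' @param curves A long curve tibble.
#' @param path File path.
#' @return `write_curves()` returns `path` invisibly; `read_curves()`
#'   returns the curve tibble.
#' @examples
#' crv <- simulate_curve(blade_design(30, 80, 30, 11, 11), 20000)
#' p <- tempfile(fileext = ".csv")
#' write_curves(crv, p)
#' read_curves(p)
#' @export
write_curves <- function(curves, path) {
  need <- c("design_id", "omega_rpm", "q_lpm", "dp_mmhg", "eta")
  miss <- setdiff(need, names(curves))
  if (length(miss) > 0) {
    abort_validation(paste0("curves are missing columns: ",
                            paste(miss, collapse = ", ")))
  }
  readr::write_csv(curves[, need], path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(design_id = readr::col_character()))
}

#' Serialise a fitted surrogate to JSON
#'
#' Writes the fitted state (coefficients, hyperparameters or weights), the
#' training normalisation, metrics and seed with explicit unit-bearing key
#' names, enough to audit or re-load the predictor.
#'
#' @param model A fitted `pump_surrogate`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_surrogate_json <- function(model, path) {
  stopifnot(inherits(model, "pump_surrogate"))
  state <- list(
    kind = model$kind,
    coefficients = as.list(model$coefficients),
    hyperparameters = as.list(model$hyperparameters),
    weights = model$weights,
    n_hidden = model$n_hidden,
    alpha = model$alpha,
    beta = model$beta,
    gamma_effective_parameters = model$gamma,
    normalisation = list(
      features = model$normalisation$features,
      target_eta = as.list(model$normalisation$target)
    ),
    metrics_eta_scale = model$metrics,
    n_designs = model$n,
    seed = model$seed
  )
  state <- state[!purrr::map_lgl(state, is.null)]
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the pipeline report to disk
#'
#' Emits a JSON summary, the tabular artefacts as CSV (designs, simulation
#' curves, scaled curves, dataset, per-combination results, GA fitness
#' histories, retargeted efficiencies), a Markdown summary table and a
#' plain-text log with timestamps. The summary records the configuration
#' hash, the master seed and the package version so a run can be
#' reproduced.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if missing; must be writable).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  log_line <- function(msg) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
        file = log_path, append = TRUE)
  }
  log_line("writing report")

  write_designs(report$baseline$designs, file.path(outdir, "designs.csv"))
  write_curves(report$baseline$curves, file.path(outdir, "curves.csv"))
  write_curves(report$baseline$scaled_curves,
               file.path(outdir, "scaled_curves.csv"))
  readr::write_csv(report$baseline$dataset, file.path(outdir, "dataset.csv"))
  readr::write_csv(report$results, file.path(outdir, "results.csv"))
  if (!is.null(report$retargeted)) {
    readr::write_csv(report$retargeted, file.path(outdir, "retargeted.csv"))
  }
  ok <- !purrr::map_lgl(report$optimisations, inherits, "error")
  for (o in report$optimisations[ok]) {
    readr::write_csv(
      o$ga$history,
      file.path(outdir, sprintf("history_%s_iter%d.csv",
                                tolower(o$row$surrogate), o$row$iteration))
    )
  }

  cfg <- report$config
  summary <- list(
    package_version = as.character(utils::packageVersion("bladeforge")),
    config_hash = rlang::hash(cfg),
    master_seed = cfg$seed,
    target_op = unclass(cfg$target_op),
    simulation_speed_rpm = cfg$simulation_speed_rpm,
    baseline = as.list(report$baseline$baseline),
    failed_scalings = report$baseline$failed,
    results = report$results,
    best = if (!is.null(report$best)) as.list(report$best),
    retargeted = report$retargeted
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  md <- c(
    "# Optimisation summary", "",
    sprintf("Baseline (best of %d factorial designs): `%s`, eta = %.4f",
            nrow(report$baseline$dataset), report$baseline$baseline$design_id,
            report$baseline$baseline$eta_at_op), "",
    "| surrogate | iteration | predicted eta | simulated eta | rel. error % | status |",
    "|---|---|---|---|---|---|",
    purrr::pmap_chr(
      report$results[, c("surrogate", "iteration", "predicted_eta",
                         "simulated_eta", "rel_error_pct", "status")],
      function(surrogate, iteration, predicted_eta, simulated_eta,
               rel_error_pct, status) {
        sprintf("| %s | %s | %.4f | %.4f | %.2f | %s |",
                surrogate, iteration, predicted_eta, simulated_eta,
                rel_error_pct, status)
      }
    )
  )
  writeLines(md, file.path(outdir, "summary.md"))
  log_line("report complete")
  invisible(outdir)
}

#' Export a camber line as a plain-text point list
#'
#' Writes `x_mm y_mm` pairs, one per line, for plotting or CAD import.
#'
#' @param arc A [camber_arc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_camber_points <- function(arc, path) {
  stopifnot(inherits(arc, "camber_arc"))
  readr::write_delim(arc$points, path, delim = " ", col_names = FALSE)
  invisible(path)
}
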