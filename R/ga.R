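#' Genetic-algorithm configuration
#'
#' Settings of the real-coded genetic algorithm used to minimise the negated
#' predicted efficiency: population size 50, crossover fraction 0.8 and
#' Gaussian mutation, converging when the relative change in the
#' generation-best objective over a stall window is at most `1e-6`.
#' Selection is rank-scaled stochastic-universal sampling with elitism;
#' mutation noise has per-coordinate standard deviation
#' `scale * box width`, shrunk linearly by `shrink` over the run.
#'
#' @param population_size Individuals per generation.
#' @param crossover_fraction Fraction of non-elite offspring produced by
#'   intermediate crossover (the remainder by mutation), in `[0, 1]`.
#' @param mutation_scale,mutation_shrink Initial mutation scale and linear
#'   shrink factor, both relative to the box width.
#' @param elite_count Individuals copied unchanged each generation
#'   (must be below `population_size`).
#' @param convergence_tol Relative best-objective change threshold.
#' @param stall_generations Window over which the change is measured.
#' @param max_generations Hard generation cap.
#' @param seed Integer seed; identical seed, config and objective give an
#'   identical result.
#' @return An object of class `ga_config`.
#' @examples
#' ga_config(seed = 1)
#' @export
ga_config <- function(population_size = 50, crossover_fraction = 0.8,
                      mutation_scale = 1.0, mutation_shrink = 1.0,
                      elite_count = 3, convergence_tol = 1e-6,
                      stall_generations = 50, max_generations = 500,
                      seed = 1) {
  if (crossover_fraction < 0 || crossover_fraction > 1) {
    abort_validation("crossover_fraction must lie in [0, 1]")
  }
  if (elite_count >= population_size) {
    abort_validation("elite_count must be smaller than population_size")
  }
  if (convergence_tol <= 0) abort_validation("convergence_tol must be positive")
  structure(
    list(population_size = population_size,
         crossover_fraction = crossover_fraction,
         mutation_scale = mutation_scale, mutation_shrink = mutation_shrink,
         elite_count = elite_count, convergence_tol = convergence_tol,
         stall_generations = stall_generations,
         max_generations = max_generations, seed = seed),
    class = "ga_config"
  )
}

# clamp to the box, then restore blade orientation by lifting beta2 just
# above beta1 (capped at 90)
ga_repair <- function(pop, lower, upper) {
  pop <- pmin(pmax(pop, matrix(lower, nrow(pop), 5, byrow = TRUE)),
              matrix(upper, nrow(pop), 5, byrow = TRUE))
  bad <- pop[, 2] <= pop[, 1]
  if (any(bad)) {
    pop[bad, 2] <- pmin(90, pop[bad, 1] + 1e-3)
  }
  pop
}

pop_to_designs <- function(pop) {
  colnames(pop) <- DESIGN_PARAMS
  d <- tibble::as_tibble(pop)
  dplyr::mutate(d, design_id = sprintf("x%03d", dplyr::row_number()),
                .before = 1)
}

# stochastic-universal sampling of n indices given selection probabilities
sus_select <- function(prob, n) {
  edges <- cumsum(prob)
  pointers <- (stats::runif(1) + seq_len(n) - 1) / n
  idx <- findInterval(pointers, edges) + 1
  sample(idx) # shuffle so pairing is unbiased
}

#' Minimise an objective over blade designs with a genetic algorithm
#'
#' Real-coded GA over the five governing parameters, subject to the box
#' bounds of one constraint iteration and the linear blade-orientation
#' constraint beta2 > beta1. Offspring are projected onto the box and
#' repaired before evaluation, so the objective is only ever called on
#' feasible designs. Elitism makes the generation-best objective
#' non-increasing.
#'
#' @param objective A function taking a designs tibble and returning a
#'   numeric vector to be minimised (e.g. negated surrogate efficiency; see
#'   [surrogate_objective()]).
#' @param box A [constraint_box()].
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best_design` (one-row designs
#'   tibble), `best_fitness`, `generations`, `history` (tibble of
#'   generation-best fitness), `feasibility` (from [validate_designs()]),
#'   `converged` and `seed`.
#' @examples
#' obj <- function(d) (d$beta1_deg - 30)^2 + (d$alpha2_deg - 30)^2
#' res <- ga_optimize(obj, constraint_box(0),
#'                    ga_config(max_generations = 60, seed = 1))
#' res$best_design
#' @export
ga_optimize <- function(objective, box, config = ga_config()) {
  b <- box_bounds(box)
  lower <- unname(b$lower)
  upper <- unname(b$upper)
  if (upper[2] <= lower[1]) {
    abort_validation("infeasible box: no design can satisfy beta2 > beta1")
  }
  np <- config$population_size
  ne <- config$elite_count
  width <- upper - lower

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  pop <- matrix(stats::runif(np * 5), np, 5)
  pop <- sweep(sweep(pop, 2, width, "*"), 2, lower, "+")
  pop <- ga_repair(pop, lower, upper)
  fitness <- objective(pop_to_designs(pop))

  history <- numeric(config$max_generations)
  converged <- FALSE
  gen <- 0

  n_children <- np - ne
  n_xover <- round(config$crossover_fraction * n_children)
  n_mut <- n_children - n_xover

  for (gen in seq_len(config$max_generations)) {
    ord <- order(fitness)
    pop <- pop[ord, , drop = FALSE]
    fitness <- fitness[ord]
    history[gen] <- fitness[1]

    # convergence: relative change of the generation best over the stall
    # window
    if (gen > config$stall_generations) {
      f_now <- history[gen]
      f_then <- history[gen - config$stall_generations]
      if (abs(f_now - f_then) / max(abs(f_now), 1e-12) <= config$convergence_tol) {
        converged <- TRUE
        break
      }
    }

    scores <- 1 / sqrt(seq_len(np)) # rank scaling on the sorted population
    prob <- scores / sum(scores)
    parents <- sus_select(prob, 2 * n_xover + n_mut)

    children <- matrix(NA_real_, n_children, 5)
    if (n_xover > 0) {
      p1 <- pop[parents[seq_len(n_xover)], , drop = FALSE]
      p2 <- pop[parents[n_xover + seq_len(n_xover)], , drop = FALSE]
      u <- matrix(stats::runif(n_xover * 5), n_xover, 5)
      children[seq_len(n_xover), ] <- p1 + u * (p2 - p1)
    }
    if (n_mut > 0) {
      pm <- pop[parents[2 * n_xover + seq_len(n_mut)], , drop = FALSE]
      sd_gen <- config$mutation_scale *
        max(0, 1 - config$mutation_shrink * gen / config$max_generations)
      noise <- matrix(stats::rnorm(n_mut * 5), n_mut, 5) *
        matrix(sd_gen * width, n_mut, 5, byrow = TRUE)
      children[n_xover + seq_len(n_mut), ] <- pm + noise
    }
    children <- ga_repair(children, lower, upper)
    child_fitness <- objective(pop_to_designs(children))

    pop <- rbind(pop[seq_len(ne), , drop = FALSE], children)
    fitness <- c(fitness[seq_len(ne)], child_fitness)
  }

  best_i <- which.min(fitness)
  best <- pop_to_designs(pop[best_i, , drop = FALSE])
  best$design_id <- "ga_best"
  structure(
    list(
      best_design = best,
      best_fitness = fitness[best_i],
      generations = gen,
      history = tibble::tibble(generation = seq_len(gen),
                               best_fitness = cummin(history[seq_len(gen)])),
      feasibility = validate_designs(best, box),
      converged = converged,
      box = box,
      seed = config$seed
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best objective %.6g after %d generations%s\n",
              x$best_fitness, x$generations,
              if (x$converged) " (converged)" else " (generation cap)"))
  print(x$best_design)
  invisible(x)
}

#' Negated-efficiency objective from a surrogate
#'
#' Wraps a fitted surrogate as the GA objective: the genetic algorithm
#' minimises, so the predicted efficiency is negated.
#'
#' @param model A fitted `pump_surrogate`.
#' @return A function mapping a designs tibble to negated predicted
#'   efficiency.
#' @export
surrogate_objective <- function(model) {
  force(model)
  function(designs) -predict(model, designs)
}

#' Repeatability of the GA solution across seeds
#'
#' Runs [ga_optimize()] `n_repeats` times with distinct seeds and reports,
#' per parameter, the maximum relative spread `100 * (max - min) / max` of
#' the returned solutions, compared against a tolerance (default 1%, the
#' conventional repeatability bound for this optimisation). A flat
#' objective -- where the best objective value barely varies while the
#' solutions scatter -- is flagged as non-identifiable rather than passed.
#'
#' @param objective,box,config As in [ga_optimize()].
#' @param n_repeats Number of repeats (>= 2, default 5).
#' @param seeds Optional explicit seeds (length `n_repeats`); defaults to
#'   `config$seed + 0:(n_repeats - 1)`.
#' @param tolerance_pct Spread threshold in percent.
#' @return An object of class `ga_repeatability`: a list with `spread`
#'   (tibble of per-parameter spread %), `max_spread_pct`,
#'   `within_tolerance`, `non_identifiable`, `solutions` and `results`.
#' @export
ga_repeatability <- function(objective, box, config = ga_config(),
                             n_repeats = 5, seeds = NULL,
                             tolerance_pct = 1) {
  if (n_repeats < 2) abort_validation("n_repeats must be at least 2")
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_repeats) - 1
  stopifnot(length(seeds) == n_repeats)
  results <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    ga_optimize(objective, box, cfg)
  })
  sols <- dplyr::bind_rows(purrr::map(results, "best_design"))
  spread <- tibble::tibble(
    parameter = DESIGN_PARAMS,
    spread_pct = purrr::map_dbl(DESIGN_PARAMS, function(p) {
      v <- sols[[p]]
      100 * (max(v) - min(v)) / max(v)
    })
  )
  fits <- purrr::map_dbl(results, "best_fitness")
  rel_fit_spread <- (max(fits) - min(fits)) / max(abs(fits), 1e-300)
  max_spread <- max(spread$spread_pct)
  structure(
    list(
      spread = spread,
      max_spread_pct = max_spread,
      tolerance_pct = tolerance_pct,
      within_tolerance = max_spread <= tolerance_pct,
      non_identifiable = max_spread > tolerance_pct && rel_fit_spread < 1e-9,
      best_fitness = fits,
      solutions = sols,
      results = results,
      seeds = seeds
    ),
    class = "ga_repeatability"
  )
}

#' @export
print.ga_repeatability <- function(x, ...) {
  cat(sprintf("<ga_repeatability> %d repeats, max parameter spread %.4g%% (tolerance %g%%): %s\n",
              length(x$best_fitness), x$max_spread_pct, x$tolerance_pct,
              if (x$non_identifiable) "non-identifiable objective"
              else if (x$within_tolerance) "within tolerance" else "exceeds tolerance"))
  print(x$spread)
  invisible(x)
}
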