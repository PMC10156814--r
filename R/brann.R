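# Bayesian-regularised single-hidden-layer network trained by
# Levenberg-Marquardt on the regularised objective F = beta * E_D + alpha *
# E_W (E_D the sum of squared errors, E_W the sum of squared weights), with
# alpha and beta re-estimated each accepted step from the Gauss-Newton
# approximation to the evidence: gamma = p - 2 alpha tr(H^-1),
# alpha = gamma / (2 E_W), beta = (N - gamma) / (2 E_D). The network is
# tiny (5 -> n_hidden tanh -> 1 linear), so the Jacobian is formed
# analytically and the normal equations solved densely.

brann_unpack <- function(w, n_in, n_hidden) {
  i1 <- n_hidden * n_in
  list(
    w1 = matrix(w[seq_len(i1)], n_hidden, n_in),
    b1 = w[i1 + seq_len(n_hidden)],
    w2 = w[i1 + n_hidden + seq_len(n_hidden)],
    b2 = w[i1 + 2 * n_hidden + 1]
  )
}

brann_forward <- function(w, x, n_hidden) {
  p <- brann_unpack(w, ncol(x), n_hidden)
  a <- tanh(sweep(x %*% t(p$w1), 2, p$b1, "+"))
  list(yhat = drop(a %*% p$w2) + p$b2, a = a)
}

# Jacobian of the network output w.r.t. the weight vector, N x p
brann_jacobian <- function(w, x, n_hidden) {
  n_in <- ncol(x)
  p <- brann_unpack(w, n_in, n_hidden)
  fwd <- brann_forward(w, x, n_hidden)
  d <- (1 - fwd$a^2) * matrix(p$w2, nrow(x), n_hidden, byrow = TRUE) # N x h
  j_w1 <- do.call(cbind, purrr::map(seq_len(n_hidden), function(h) d[, h] * x))
  # j_w1 columns are ordered (h, i) = (1,1..n_in), (2,1..n_in), ...; the
  # weight vector stores matrix(w1, n_hidden, n_in) column-major, i.e.
  # weight (h, i) at index (i - 1) * n_hidden + h -- permute to match
  perm <- as.vector(matrix(seq_len(n_hidden * n_in), n_hidden, n_in,
                           byrow = TRUE))
  j_w1 <- j_w1[, perm, drop = FALSE]
  cbind(j_w1, d, fwd$a, 1)
}

brann_train <- function(x, y, n_hidden, seed, evidence = TRUE,
                        alpha0 = 0, beta0 = 1, max_iter = 300,
                        warmup = 25) {
  n <- nrow(x)
  n_in <- ncol(x)
  p <- n_hidden * n_in + 2 * n_hidden + 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  w <- stats::runif(p, -0.5, 0.5)

  alpha <- alpha0
  beta <- beta0
  mu <- 0.005
  mu_max <- 1e10
  gamma <- p
  converged <- FALSE
  e_d_prev <- Inf

  err <- y - brann_forward(w, x, n_hidden)$yhat
  f_old <- beta * sum(err^2) + alpha * sum(w^2)

  for (iter in seq_len(max_iter)) {
    j <- brann_jacobian(w, x, n_hidden)
    err <- y - brann_forward(w, x, n_hidden)$yhat
    grad <- 2 * beta * crossprod(j, err) - 2 * alpha * w # descent direction
    jtj <- crossprod(j)
    accepted <- FALSE
    while (mu <= mu_max) {
      h_lm <- 2 * beta * jtj + diag(2 * alpha + mu, p)
      step <- tryCatch(solve(h_lm, grad), error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + drop(step)
        err_new <- y - brann_forward(w_new, x, n_hidden)$yhat
        f_new <- beta * sum(err_new^2) + alpha * sum(w_new^2)
        if (is.finite(f_new) && f_new < f_old) {
          w <- w_new
          err <- err_new
          mu <- max(mu * 0.1, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break # mu exhausted: cannot reduce F further

    if (evidence && iter >= warmup) {
      # gamma from the regularised Gauss-Newton Hessian (alpha floored so
      # that null directions of J'J count as unused parameters even while
      # alpha is still 0), then (alpha, beta) from the evidence formulas;
      # the cap gamma <= n - 1 keeps the re-estimated beta positive even
      # when the network has more weights than training rows
      e_w <- max(sum(w^2), 1e-12)
      e_d <- max(sum(err^2), 1e-12)
      alpha_eff <- max(alpha, 1e-10)
      h <- 2 * beta * crossprod(brann_jacobian(w, x, n_hidden)) +
        diag(2 * alpha_eff, p)
      tr_inv <- tryCatch(sum(diag(solve(h))), error = function(e) NA_real_)
      if (is.finite(tr_inv)) gamma <- p - 2 * alpha_eff * tr_inv
      alpha <- min(gamma, n - 1) / (2 * e_w)
      beta <- max(n - min(gamma, n - 1), 1e-3) / (2 * e_d)
      f_old <- beta * e_d + alpha * e_w
      # stop once the data misfit has stabilised under the evidence updates
      if (e_d < 1e-16 ||
          (is.finite(e_d_prev) &&
           abs(e_d - e_d_prev) <= 1e-10 * max(e_d_prev, 1e-12))) {
        converged <- TRUE
        break
      }
      e_d_prev <- e_d
    } else if (evidence) {
      # warm-up: pure Levenberg-Marquardt on the data term before the
      # evidence updates switch the regularisation on
      f_old <- beta * sum(err^2) + alpha * sum(w^2)
    } else {
      f_new <- beta * sum(err^2) + alpha * sum(w^2)
      if (abs(f_old - f_new) <= 1e-12 * max(abs(f_old), 1e-12)) {
        converged <- TRUE
        f_old <- f_new
        break
      }
      f_old <- f_new
    }
    if (evidence && sum(grad^2) < 1e-14) {
      converged <- TRUE
      break
    }
  }
  if (!converged && mu > mu_max) converged <- TRUE # objective locally minimal
  list(weights = w, alpha = alpha, beta = beta, gamma = gamma,
       converged = converged, n_iter = iter)
}

#' Bayesian-regularised neural-network surrogate
#'
#' Trains a single-hidden-layer network (five tanh neurons by default,
#' linear output) on the normalised dataset by Levenberg-Marquardt
#' minimisation of the Bayesian-regularised objective
#' `beta * E_D + alpha * E_W`, with the regularisation hyperparameters
#' updated by the Gauss-Newton evidence approximation. The regularisation
#' suppresses over-fitting, so validation needs only a simple holdout: a
#' random 15% of the designs (5 of 32) is withheld from training and its
#' RMSE reported alongside the training and all-data RMSEs, on the natural
#' efficiency scale. The effective number of parameters `gamma` measures how
#' many weights the evidence actually uses.
#'
#' @param data A [build_design_dataset()] object.
#' @param n_hidden Hidden-layer width (default 5).
#' @param holdout_fraction Fraction of designs withheld (default 0.15,
#'   giving exactly 5 of 32).
#' @param seed Integer seed (weight initialisation and holdout draw);
#'   identical seeds give bit-identical fits.
#' @param max_iter Levenberg-Marquardt iteration cap; non-convergence
#'   returns the model with a warning flag.
#' @return An object of class `c("brann_surrogate", "pump_surrogate")` with
#'   the weight vector, `alpha`, `beta`, `gamma`, holdout indices and
#'   `metrics` (`rmse_train`, `rmse_holdout`, `rmse_all`).
#' @examples
#' # see build_design_dataset() for dataset construction
#' @export
fit_brann <- function(data, n_hidden = 5, holdout_fraction = 0.15, seed = 1,
                      max_iter = 300) {
  stopifnot(inherits(data, "design_dataset"))
  if (n_hidden < 1) abort_validation("n_hidden must be at least 1")
  n <- nrow(data)
  n_hold <- round(n * holdout_fraction)
  if (n_hold < 1 || n_hold >= n) {
    abort_validation("holdout_fraction must leave at least one test and one training row")
  }
  norm <- attr(data, "normalisation")
  x <- normalise_features(data, norm)
  y <- normalise_target(data$eta_at_op, norm)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hold <- sort(sample.int(n, n_hold))
  tr <- setdiff(seq_len(n), hold)

  fit <- brann_train(x[tr, , drop = FALSE], y[tr], n_hidden, seed = seed + 1,
                     max_iter = max_iter)
  if (!fit$converged) {
    rlang::warn("BRANN training hit max_iter without meeting the convergence test")
  }
  pred <- brann_forward(fit$weights, x, n_hidden)$yhat
  structure(
    list(
      kind = "BRANN",
      n_hidden = n_hidden,
      weights = fit$weights,
      alpha = fit$alpha,
      beta = fit$beta,
      gamma = fit$gamma,
      converged = fit$converged,
      n_iter = fit$n_iter,
      holdout = hold,
      holdout_ids = data$design_id[hold],
      normalisation = norm,
      metrics = list(
        rmse_train = natural_rmse(pred[tr] - y[tr], norm),
        rmse_holdout = natural_rmse(pred[hold] - y[hold], norm),
        rmse_all = natural_rmse(pred - y, norm)
      ),
      n = n,
      seed = seed
    ),
    class = c("brann_surrogate", "pump_surrogate")
  )
}

#' @export
surrogate_eval.brann_surrogate <- function(object, xnorm) {
  brann_forward(object$weights, xnorm, object$n_hidden)$yhat
}
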