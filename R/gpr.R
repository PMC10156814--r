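# Gaussian-process regression with a constant (profiled) mean and isotropic
# stationary kernels over the normalised [-1, 1]^5 feature space. Written in
# plain linear algebra: the datasets here are tiny (n ~ 32), so Cholesky
# factorisations cost nothing and nothing beyond base R is needed.

GPR_KERNELS <- c("matern52", "sqexp", "exp", "rationalquadratic")

kernel_fn <- function(kernel) {
  switch(kernel,
    matern52 = function(r, ell, extra) {
      s <- sqrt(5) * r / ell
      (1 + s + s^2 / 3) * exp(-s)
    },
    sqexp = function(r, ell, extra) exp(-r^2 / (2 * ell^2)),
    exp = function(r, ell, extra) exp(-r / ell),
    rationalquadratic = function(r, ell, extra) {
      (1 + r^2 / (2 * extra * ell^2))^(-extra)
    },
    abort_validation(sprintf("unknown kernel '%s'", kernel))
  )
}

pair_dist <- function(a, b) {
  # Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

gpr_cov <- function(dist, theta, kernel) {
  theta$sf^2 * kernel_fn(kernel)(dist, theta$ell, theta$alpha)
}

# Cholesky with escalating jitter, 1e-10 * 10^k up to 1e-6
chol_jitter <- function(k_mat) {
  n <- nrow(k_mat)
  jitter <- 0
  for (j in c(0, 1e-10 * 10^(0:4))) {
    l <- tryCatch(chol(k_mat + diag(j, n)), error = function(e) NULL)
    if (!is.null(l)) return(list(chol = l, jitter = j))
  }
  rlang::abort("kernel matrix is not positive definite after jitter escalation",
               class = "bladeforge_error_gpr")
}

# negative log marginal likelihood with the constant mean profiled out by
# generalised least squares
gpr_nll <- function(log_par, dist, y, kernel) {
  theta <- gpr_unpack(log_par, kernel)
  k_mat <- gpr_cov(dist, theta, kernel) + diag(theta$sn^2, length(y))
  l <- tryCatch(chol(k_mat + diag(1e-10, length(y))),
                error = function(e) NULL)
  if (is.null(l)) return(1e10)
  a1 <- backsolve(l, forwardsolve(t(l), rep(1, length(y))))
  ay <- backsolve(l, forwardsolve(t(l), y))
  mu <- sum(a1 * y) / sum(a1 * rep(1, length(y)))
  r <- y - mu
  ar <- backsolve(l, forwardsolve(t(l), r))
  0.5 * sum(r * ar) + sum(log(diag(l))) + 0.5 * length(y) * log(2 * pi)
}

gpr_unpack <- function(log_par, kernel) {
  theta <- list(ell = exp(log_par[1]), sf = exp(log_par[2]),
                sn = exp(log_par[3]), alpha = NA_real_)
  if (kernel == "rationalquadratic") theta$alpha <- exp(log_par[4])
  theta
}

gpr_opt <- function(x, y, kernel) {
  dist <- pair_dist(x, x)
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  base_starts <- list(
    c(log(1), log(sy), log(1e-3)),
    c(log(3), log(sy), log(1e-2)),
    c(log(0.3), log(sy), log(1e-4))
  )
  npar <- if (kernel == "rationalquadratic") 4 else 3
  lower <- c(log(1e-2), log(1e-3), log(1e-6), log(1e-2))[1:npar]
  upper <- c(log(1e2), log(1e2), log(1), log(1e2))[1:npar]
  best <- NULL
  for (s in base_starts) {
    if (npar == 4) s <- c(s, log(1))
    fit <- tryCatch(
      stats::optim(s, gpr_nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, dist = dist, y = y, kernel = kernel,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    rlang::abort("GPR hyperparameter optimisation failed for every start",
                 class = "bladeforge_error_gpr")
  }
  theta <- gpr_unpack(best$par, kernel)
  theta$nll <- best$value
  theta
}

gpr_posterior <- function(x, y, theta, kernel) {
  n <- length(y)
  k_mat <- gpr_cov(pair_dist(x, x), theta, kernel) + diag(theta$sn^2, n)
  cj <- chol_jitter(k_mat)
  l <- cj$chol
  a1 <- backsolve(l, forwardsolve(t(l), rep(1, n)))
  mu <- sum(a1 * y) / sum(a1)
  alpha_vec <- backsolve(l, forwardsolve(t(l), y - mu))
  list(x = x, mu = mu, alpha = alpha_vec, theta = theta, jitter = cj$jitter)
}

gpr_predict_norm <- function(post, xnew, kernel) {
  ks <- gpr_cov(pair_dist(xnew, post$x), post$theta, kernel)
  drop(ks %*% post$alpha) + post$mu
}

#' Gaussian-process regression surrogate
#'
#' Fits a GP regression ("simple kriging") surrogate of design-point
#' efficiency on the five normalised geometry parameters, with a constant
#' (trained) mean, an isotropic stationary kernel and a fitted noise term.
#' Hyperparameters maximise the log marginal likelihood. Validation follows
#' a k-fold cross-validation protocol: the data are partitioned into
#' `n_folds` folds, hyperparameters are refitted on each training split and
#' the held-out RMSE recorded; the reported validation RMSE is the mean over
#' folds, and the final model is refitted on all data (its resubstitution
#' RMSE is reported separately). The Matern 5/2 kernel is the default; see
#' [compare_gpr_kernels()] for the four-kernel comparison.
#'
#' @param data A [build_design_dataset()] object with at least `n_folds`
#'   rows.
#' @param kernel One of `"matern52"`, `"sqexp"`, `"exp"`,
#'   `"rationalquadratic"`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `c("gpr_surrogate", "pump_surrogate")` with
#'   `hyperparameters`, the fitted posterior state, and `metrics`
#'   (`rmse_validation`, per-fold RMSEs, `rmse_all`; natural efficiency
#'   scale).
#' @examples
#' # see build_design_dataset() for dataset construction
#' @export
fit_gpr <- function(data, kernel = "matern52", n_folds = 5, seed = 1) {
  stopifnot(inherits(data, "design_dataset"))
  kernel <- match.arg(kernel, GPR_KERNELS)
  n <- nrow(data)
  if (n < n_folds) abort_validation("fit_gpr needs at least n_folds designs")
  norm <- attr(data, "normalisation")
  x <- normalise_features(data, norm)
  y <- normalise_target(data$eta_at_op, norm)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))

  span <- diff(range(data$eta_at_op))
  fold_rmse <- purrr::map_dbl(seq_len(n_folds), function(k) {
    tr <- fold != k
    theta_k <- gpr_opt(x[tr, , drop = FALSE], y[tr], kernel)
    post_k <- gpr_posterior(x[tr, , drop = FALSE], y[tr], theta_k, kernel)
    pred <- gpr_predict_norm(post_k, x[!tr, , drop = FALSE], kernel)
    natural_rmse(pred - y[!tr], norm)
  })

  theta <- gpr_opt(x, y, kernel)
  post <- gpr_posterior(x, y, theta, kernel)
  resid <- gpr_predict_norm(post, x, kernel) - y
  structure(
    list(
      kind = "GPR",
      kernel = kernel,
      hyperparameters = c(lengthscale = theta$ell, signal_sd = theta$sf,
                          noise_sd = theta$sn, rq_alpha = theta$alpha),
      posterior = post,
      normalisation = norm,
      metrics = list(
        rmse_validation = mean(fold_rmse),
        rmse_folds = fold_rmse,
        rmse_all = natural_rmse(resid, norm)
      ),
      n = n,
      seed = seed
    ),
    class = c("gpr_surrogate", "pump_surrogate")
  )
}

#' @export
surrogate_eval.gpr_surrogate <- function(object, xnorm) {
  gpr_predict_norm(object$posterior, xnorm, object$kernel)
}

#' Compare GPR kernels by cross-validated RMSE
#'
#' Fits [fit_gpr()] with each candidate kernel under the same fold seed and
#' ranks kernels by validation RMSE, the protocol used to select the
#' Matern 5/2 kernel.
#'
#' @inheritParams fit_gpr
#' @param kernels Character vector of kernels to compare.
#' @return A tibble (`kernel`, `rmse_validation`, `rmse_all`) sorted by
#'   validation RMSE, with attribute `models`.
#' @export
compare_gpr_kernels <- function(data, kernels = GPR_KERNELS, n_folds = 5,
                                seed = 1) {
  models <- purrr::map(kernels, ~ fit_gpr(data, .x, n_folds, seed))
  out <- tibble::tibble(
    kernel = kernels,
    rmse_validation = purrr::map_dbl(models, ~ .x$metrics$rmse_validation),
    rmse_all = purrr::map_dbl(models, ~ .x$metrics$rmse_all)
  )
  out <- dplyr::arrange(out, .data$rmse_validation)
  attr(out, "models") <- stats::setNames(models, kernels)
  out
}
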