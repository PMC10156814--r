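# Independent oracles and shared fixtures for the test suite. These stay
# deliberately naive (normal equations, bisection, brute-force grids) so
# they check the implementation without sharing code paths with it.

mid_design <- function() {
  blade_design(32.5, 82.5, 32.5, 11.5, 11.5, design_id = "mid")
}

random_box_designs <- function(n, seed, box = constraint_box(0)) {
  set.seed(seed)
  lo <- box$min
  hi <- box$max
  m <- sapply(1:5, function(j) runif(n, lo[j], hi[j]))
  # enforce blade orientation by resampling beta2 above beta1
  m[, 2] <- pmin(90, pmax(m[, 2], m[, 1] + runif(n, 1, 20)))
  blade_design(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5],
               design_id = sprintf("r%03d", seq_len(n)))
}

# least-squares quartic through the normal equations (oracle for fit_quartic)
normal_equations_quartic <- function(q, dp) {
  x <- cbind(q^4, q^3, q^2, q, 1)
  solve(t(x) %*% x, t(x) %*% dp)[, 1]
}

# bisection root of f on [lo, hi] (oracle for the polynomial match point)
bisect_root <- function(f, lo, hi, tol = 1e-13) {
  flo <- f(lo)
  fhi <- f(hi)
  stopifnot(flo * fhi <= 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol * max(1, abs(mid))) break
    if (flo * fm <= 0) {
      hi <- mid
      fhi <- fm
    } else {
      lo <- mid
      flo <- fm
    }
  }
  (lo + hi) / 2
}

# nearest-neighbour regression baseline (oracle floor for GPR accuracy)
nn_predict <- function(x_train, y_train, x_new) {
  apply(x_new, 1, function(row) {
    d <- rowSums((x_train - matrix(row, nrow(x_train), ncol(x_train),
                                   byrow = TRUE))^2)
    y_train[which.min(d)]
  })
}

# a baseline run is reused across several test files; cached per session
cached_baseline <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- suppressWarnings(run_baseline(pipeline_config(seed = 1)))
    }
    value
  }
})

expect_no_mismatch <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
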