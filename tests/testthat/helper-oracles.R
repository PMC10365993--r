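# Independent oracles used across test files.

# Dense-matrix evaluation of the weighted least-squares estimator and the
# Huber-White sandwich variance, straight from the defining formulas.
wls_sandwich_oracle <- function(X, y, w) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  D <- diag(as.numeric(y - X %*% beta)^2)
  V <- solve(XtWX) %*% (t(X) %*% W %*% D %*% W %*% X) %*% solve(XtWX)
  list(beta = as.numeric(beta), vcov = V)
}

# Small cohort with a known single-trait collider structure.
make_toy_cohort <- function(n = 2000, loading_var = "education",
                            loading = 0.7, seed = 1) {
  y <- withr::with_seed(seed, rnorm(n))
  L <- matrix(loading, 1, 1, dimnames = list(loading_var, NULL))
  aux <- simulate_auxiliary(cbind(y), L, seed = seed + 1)
  aux$id <- sprintf("i%05d", seq_len(n))
  list(cohort = aux, trait = y)
}

# Horvitz-Thompson estimate of a population mean from a weighted sample.
ht_mean <- function(x, w) sum(w * x) / sum(w)

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", value, target, tol))
}
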