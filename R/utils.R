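# Internal helpers shared across modules.

#' @importFrom stats rnorm rbinom runif qnorm pnorm dnorm plogis quantile
#'   var sd cor coef predict uniroot pchisq p.adjust complete.cases glm
#'   binomial quasibinomial
#' @importFrom utils head combn
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seeded <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ipw <- function(...) stop(sprintf(...), call. = FALSE)
warn_ipw <- function(...) warning(sprintf(...), call. = FALSE)

assert_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_ipw("%s must be numeric and non-missing", name)
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad) stop_ipw("%s must lie strictly inside (0, 1)", name)
  invisible(x)
}

# Weighted Pearson correlation (population-style weighting).
weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cx <- sum(w * (x - mx)^2)
  cy <- sum(w * (y - my)^2)
  cxy / sqrt(cx * cy)
}

# Monte-Carlo standard error of a weighted mean (ratio-estimator form).
weighted_mean_se <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  sqrt(sum(w^2 * (x - m)^2)) / W
}
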