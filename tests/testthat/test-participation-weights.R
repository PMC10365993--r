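test_that("design expansion reproduces the predictor count and coding conventions", {
  tc <- make_toy_cohort(200, seed = 1)
  X <- build_design(tc$cohort)
  expect_equal(ncol(X), 903)  # 42 mains + choose(42, 2) products
  expect_equal(attr(X, "n_main"), 42L)
  # indicator columns are 0/1
  sex_col <- X[, "sex=male"]
  expect_true(all(sex_col %in% c(0, 1)))
  # same-variable indicator products are identically zero
  expect_true(all(X[, "sex=male:sex=female"] == 0))
  # a 1-continuous + 1-binary schema gives 3 mains and 3 products
  mini_spec <- data.frame(variable = c("age", "sex"),
                          type = c("continuous", "categorical"),
                          levels = I(list(NULL, c("male", "female"))))
  Xm <- build_design(tc$cohort[, c("age", "sex")], mini_spec)
  expect_equal(ncol(Xm), 6)
  # unseen level fails loudly, naming variable and level
  bad <- tc$cohort
  bad$sex <- as.character(bad$sex)
  bad$sex[1] <- "other"
  expect_error(build_design(bad), "sex.*other")
})

test_that("weight construction follows (1-P)/P with exact normalization", {
  pw <- compute_weights(c(0.5, 0.5, 0.2))
  expect_equal(pw$w, c(1, 1, 4))
  expect_equal(pw$w_in, c(0.5, 0.5, 2))
  expect_equal(mean(pw$w_in), 1)
  expect_equal(pw$W, 6)
  expect_equal(compute_weights(0.2)$w, 4)
  expect_error(compute_weights(c(0.5, 1)), "inside")
  expect_error(compute_weights(c(0.5, 0)), "inside")
  # optional cap truncates the heaviest weights
  pwc <- compute_weights(c(rep(0.5, 98), 0.01, 0.5), cap_quantile = 0.9)
  expect_lt(max(pwc$w), 99)
})

test_that("effective sample size satisfies both printed identities", {
  expect_equal(effective_sample_size(c(1, 1, 4)), 2)
  w_in <- c(1, 1, 4) / 2
  expect_equal(3 / (mean((w_in - mean(w_in))^2) + 1), 2)
  expect_equal(effective_sample_size(rep(3, 17)), 17)
  # identity property over random weight vectors
  for (s in 1:25) {
    w <- withr::with_seed(s, rlnorm(withr::with_seed(s, sample(3:50, 1))))
    n <- length(w)
    w_in <- w / mean(w)
    lhs <- sum(w_in)^2 / sum(w_in^2)
    rhs <- n / (sum((w_in - 1)^2) / n + 1)
    expect_lt(abs(lhs - rhs), 1e-10)
    expect_lte(lhs, n + 1e-12)
  }
  # duplicating an individual raises the effective size
  expect_gt(effective_sample_size(c(1, 1, 4, 4)), effective_sample_size(c(1, 1, 4)))
  expect_error(effective_sample_size(numeric(0)), "empty")
})

test_that("weighted moments are exact, scale invariant, and handle factors", {
  expect_equal(weighted_moments(c(0, 1, 1), c(2, 1, 1)), 0.5)
  expect_equal(weighted_moments(1:10, rep(2, 10)), mean(1:10))
  x <- withr::with_seed(1, rnorm(100))
  w <- withr::with_seed(2, rlnorm(100))
  expect_equal(weighted_moments(x, w), weighted_moments(x, 7.3 * w))
  f <- factor(c("a", "a", "b"))
  expect_equal(weighted_moments(f, c(1, 1, 2)), c(a = 0.5, b = 0.5))
  expect_error(weighted_moments(c(1, 2), c(0, 0)), "zero")
})

test_that("bias reduction fractions match direct arithmetic and flag degeneracy", {
  expect_equal(bias_reduction(0.2, 0.3, 0.21), 0.9, ignore_attr = TRUE)
  expect_equal(bias_reduction(0.4, 0.1, 0.4), 1, ignore_attr = TRUE)
  expect_equal(bias_reduction(0.4, 0.1, 0.1), 0, ignore_attr = TRUE)
  und <- bias_reduction(0.3, 0.3, 0.25)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(bias_reduction(1.5, 0, 0), "\\[-1, 1\\]")
})

test_that("the LASSO participation model behaves at its limits and recovers the mechanism", {
  tc <- make_toy_cohort(2500, seed = 71)
  coh <- apply_participation(tc$cohort,
                             participation_model(c(education = 0.8),
                                                 target_fraction = 0.3),
                             seed = 72)
  coh$design_weight <- 1
  sel <- coh[coh$participation == 1, ]
  ref <- draw_reference_sample(coh, 600, seed = 73)
  st <- stack_cohorts(sel, ref)
  X <- build_design(st)
  fit <- fit_participation_model(X, st$participation, seed = 74)
  # education coefficients present and sign-consistent with the generator
  cf <- fit$coefficients[-1, 1]
  edu <- cf[grepl("^education", names(cf)) & !grepl(":", names(cf))]
  expect_gt(sum(edu), 0)
  # full-shrinkage limit: all non-intercept coefficients vanish
  b_inf <- coef(fit$glmnet_fit, s = 1e6)
  expect_true(all(b_inf[-1, 1] == 0))
  # labels independent of the design: probabilities collapse to the base rate
  lab_null <- withr::with_seed(75, sample(st$participation))
  fit_null <- fit_participation_model(X, lab_null, seed = 76)
  expect_within(mean(fit_null$P), mean(lab_null), 0.02)
  expect_lt(sd(fit_null$P_all), 0.05)
  expect_error(fit_participation_model(X, rep(1, nrow(X))), "single class")
})

test_that("train-test splitting is deterministic and consistent with the full fit", {
  tc <- make_toy_cohort(1500, seed = 81)
  coh <- apply_participation(tc$cohort,
                             participation_model(c(education = 0.6, "education:age" = 0.6),
                                                 target_fraction = 0.3),
                             seed = 82)
  coh$design_weight <- 1
  st <- stack_cohorts(coh[coh$participation == 1, ],
                      draw_reference_sample(coh, 500, seed = 83))
  cv1 <- crossvalidate_weights(st, seed = 84)
  cv2 <- crossvalidate_weights(st, seed = 84)
  expect_identical(cv1$P_out_of_sample, cv2$P_out_of_sample)
  expect_identical(cv1$full, cv2$full)
  expect_equal(length(cv1$P_out_of_sample), sum(st$participation == 1))
  expect_true(all(cv1$P_out_of_sample > 0 & cv1$P_out_of_sample < 1))
})

test_that("weighted logistic balance check nulls coefficients under oracle weights", {
  tc <- make_toy_cohort(20000, seed = 91)
  coh <- apply_participation(tc$cohort,
                             participation_model(c(education = 0.8),
                                                 target_fraction = 0.08),
                             seed = 92)
  coh$design_weight <- 1
  sel <- coh[coh$participation == 1, ]
  ref <- draw_reference_sample(coh, 3000, seed = 93)
  st <- stack_cohorts(sel, ref)
  w_oracle <- (1 - sel$true_P) / sel$true_P
  chk <- weighted_logistic_check(st, w_oracle)
  edu <- chk[chk$variable == "education", ]
  # before weighting the education coefficient is strongly positive ...
  expect_gt(edu$beta_pre / edu$se_pre, 4)
  # ... and oracle weighting drives every coefficient towards zero
  expect_true(all(abs(chk$beta_post / chk$se_post) < 4))
  expect_lt(abs(edu$beta_post), abs(edu$beta_pre) / 3)
  # unit weights reproduce the unweighted coefficients
  chk1 <- weighted_logistic_check(st, rep(1, nrow(sel)))
  expect_equal(chk1$beta_post, chk1$beta_pre, tolerance = 1e-8)
})

test_that("the internal robust variance matches the sandwich package", {
  skip_if_not_installed("sandwich")
  y <- withr::with_seed(1, rbinom(300, 1, 0.4))
  x <- withr::with_seed(2, rnorm(300))
  w <- withr::with_seed(3, rlnorm(300, 0, 0.5))
  fit <- glm(y ~ x, family = quasibinomial(), weights = w)
  v_int <- ipwgwas:::robust_vcov_glm(fit)
  v_ref <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(unname(v_int), unname(v_ref), tolerance = 1e-6)
})
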