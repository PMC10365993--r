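#' Fit the LASSO participation-probability model
#'
#' Logistic LASSO regression of the participation label (selected = 1,
#' reference = 0) on the expanded design matrix, with the reference sample's
#' survey design weights entering the deviance as observation weights
#' (selected rows carry weight 1). The penalty is chosen by k-fold
#' cross-validation minimizing the cross-validated deviance; ties resolve to
#' the larger (sparser) penalty.
#'
#' @param X Design matrix from [build_design()] (rows = stacked cohort).
#' @param labels 0/1 participation labels aligned to `X`'s rows.
#' @param reference_design_weights Optional design weights for the reference
#'   rows (`labels == 0`), either a vector of `sum(labels == 0)` values or of
#'   full length; default 1.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param standardize Standardize predictors internally for the penalty
#'   (coefficients are returned on the original scale); default `TRUE`.
#' @return A `weight_fit` list: `lambda`, `coefficients` (sparse, including
#'   the intercept), `P` (fitted participation probability for the selected
#'   rows, in row order), `P_all` (all rows), `n_retained_predictors`, and
#'   the underlying `glmnet` fit for out-of-sample prediction.
#' @export
fit_participation_model <- function(X, labels, reference_design_weights = NULL,
                                    n_folds = 5L, seed = 1L,
                                    standardize = TRUE) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_ipw("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop_ipw("labels contain a single class")
  n <- nrow(X)
  obs_w <- rep(1, n)
  if (!is.null(reference_design_weights)) {
    dw <- reference_design_weights
    if (length(dw) == sum(labels == 0L)) {
      obs_w[labels == 0L] <- dw
    } else if (length(dw) == n) {
      obs_w[labels == 0L] <- dw[labels == 0L]
    } else stop_ipw("reference_design_weights has the wrong length")
    if (any(obs_w <= 0)) stop_ipw("design weights must be positive")
  }
  foldid <- local_seeded(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- glmnet::cv.glmnet(X, labels, family = "binomial", weights = obs_w,
                          foldid = foldid, standardize = standardize)
  lambda <- cv$lambda.min
  P_all <- as.numeric(predict(cv$glmnet.fit, X, s = lambda, type = "response"))
  beta <- coef(cv$glmnet.fit, s = lambda)
  structure(list(
    lambda = lambda,
    coefficients = beta,
    P = P_all[labels == 1L],
    P_all = P_all,
    n_retained_predictors = sum(beta[-1, 1] != 0),
    glmnet_fit = cv$glmnet.fit,
    cv_fit = cv
  ), class = "weight_fit")
}

#' Predict participation probabilities for new rows
#'
#' @param fit A `weight_fit`.
#' @param X_new Design matrix with the same columns as the training design.
#' @return Numeric probability vector.
#' @export
predict_participation <- function(fit, X_new) {
  stopifnot(inherits(fit, "weight_fit"))
  as.numeric(predict(fit$glmnet_fit, X_new, s = fit$lambda, type = "response"))
}

#' Construct inverse-probability participation weights
#'
#' Converts fitted participation probabilities into the weights
#' `w_i = (1 - P_i) / P_i`, an extension of standard inverse-probability
#' weights that reweights the selected sample towards its target population,
#' plus the normalized weights `w_in = w_i / mean(w_i)` (mean exactly 1) and
#' the effective sample size.
#'
#' @param P Participation probabilities strictly inside (0, 1); values
#'   outside raise an error (no silent clipping).
#' @param cap_quantile Optional upper quantile (e.g. 0.99) at which raw
#'   weights are capped before normalization; off by default.
#' @return A `probability_weights` list with `P`, `w`, `w_in`, `W = sum(w)`,
#'   `n` and `n_effective`.
#' @examples
#' pw <- compute_weights(c(0.5, 0.5, 0.2))
#' pw$w     # 1 1 4
#' pw$w_in  # 0.5 0.5 2
#' @export
compute_weights <- function(P, cap_quantile = NULL) {
  assert_prob(P, "participation probabilities")
  w <- (1 - P) / P
  if (!is.null(cap_quantile)) {
    assert_prob(cap_quantile, "cap_quantile")
    w <- pmin(w, quantile(w, cap_quantile, names = FALSE))
  }
  w_in <- w / mean(w)
  structure(list(P = P, w = w, w_in = w_in, W = sum(w),
                 n = length(w),
                 n_effective = effective_sample_size(w)),
            class = "probability_weights")
}

#' Effective sample size of a weighted sample
#'
#' For normalized weights `w_in` (mean 1) the effective sample size is
#' `W_n^2 / sum(w_in^2)` with `W_n = sum(w_in)`, which is algebraically
#' identical to `n / (Var_pop(w_in) + 1)` where `Var_pop` divides by `n`.
#' It equals `n` when all weights are equal and shrinks as the weights'
#' variance grows. The quantity is invariant to rescaling the weights.
#'
#' @param w A `probability_weights` object or a positive weight vector.
#' @return Scalar effective sample size.
#' @examples
#' effective_sample_size(c(1, 1, 4))  # 2
#' @export
effective_sample_size <- function(w) {
  if (inherits(w, "probability_weights")) w <- w$w
  if (!length(w)) stop_ipw("empty weight vector")
  if (any(w <= 0)) stop_ipw("weights must be positive")
  w_in <- w / mean(w)
  sum(w_in)^2 / sum(w_in^2)
}

#' Weighted mean or proportions of a variable
#'
#' Computes `(1/W) * sum(w_i * x_i)` with `W = sum(w_i)`; for a factor the
#' weighted proportion of each level (the weighted mean of its indicator)
#' is returned. Invariant to rescaling the weights.
#'
#' @param x Numeric vector or factor.
#' @param w Positive weights (or a `probability_weights` object).
#' @return Scalar weighted mean, or a named vector of weighted proportions.
#' @export
weighted_moments <- function(x, w) {
  if (inherits(w, "probability_weights")) w <- w$w
  if (length(x) != length(w)) stop_ipw("x and w must have equal length")
  if (all(w == 0)) stop_ipw("all weights are zero")
  if (is.factor(x) || is.character(x)) {
    f <- factor(x)
    vapply(levels(f), function(l) sum(w * (f == l)) / sum(w), numeric(1))
  } else {
    sum(w * x) / sum(w)
  }
}

#' Fraction of participation bias removed by weighting
#'
#' Participation bias in an association is measured as the absolute gap
#' between the reference-sample correlation and the selected-sample
#' correlation, `r_diff = |r_ref - r_sel|`; the fraction of that gap closed
#' by weighting is `(|r_ref - r_sel| - |r_ref - r_sel_w|) / |r_ref - r_sel|`.
#' A value of 1 means weighting fully eliminated the bias, 0 means no
#' change; the quantity is undefined when `r_ref = r_sel` and is returned as
#' `NA` with a flag (such pairs are excluded from summaries).
#'
#' @param r_ref,r_sel,r_sel_weighted Correlation coefficients in `[-1, 1]`
#'   (vectorized).
#' @return Numeric vector of bias-reduction fractions with attribute
#'   `undefined` marking zero-denominator pairs.
#' @examples
#' bias_reduction(0.2, 0.3, 0.21)  # 0.9
#' @export
bias_reduction <- function(r_ref, r_sel, r_sel_weighted) {
  if (any(abs(c(r_ref, r_sel, r_sel_weighted)) > 1 + 1e-12, na.rm = TRUE))
    stop_ipw("correlations must lie in [-1, 1]")
  denom <- abs(r_ref - r_sel)
  out <- (denom - abs(r_ref - r_sel_weighted)) / denom
  undef <- denom == 0
  out[undef] <- NA_real_
  attr(out, "undefined") <- undef
  out
}

#' Correlation matrix of the auxiliary variables
#'
#' Pearson correlations among the numeric codings of the 14 auxiliary
#' variables (continuous as-is, categorical as level index), optionally
#' weighted.
#'
#' @param cohort Cohort data frame.
#' @param weights Optional positive weights (or `probability_weights`).
#' @return 14 x 14 correlation matrix.
#' @export
aux_correlations <- function(cohort, weights = NULL) {
  z <- aux_numeric(cohort)
  if (is.null(weights)) weights <- rep(1, nrow(z))
  if (inherits(weights, "probability_weights")) weights <- weights$w
  p <- ncol(z)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(z), colnames(z))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    out[i, j] <- out[j, i] <- weighted_cor(z[, i], z[, j], weights)
  }
  out
}

#' Per-pair participation-bias report
#'
#' For every unordered pair of auxiliary variables, compares the
#' reference-sample correlation (design-weighted), the unweighted
#' selected-sample correlation and the weighted selected-sample correlation,
#' and evaluates [bias_reduction()].
#'
#' @param reference Reference cohort rows (uses `design_weight` if present).
#' @param selected Selected cohort rows.
#' @param w Probability weights for the selected rows.
#' @return Data frame with columns `var_a`, `var_b`, `r_ref`, `r_sel`,
#'   `r_sel_w`, `r_diff` and `bias_reduction`.
#' @export
bias_report <- function(reference, selected, w) {
  dw <- reference$design_weight %||% rep(1, nrow(reference))
  r_ref <- aux_correlations(reference, dw)
  r_sel <- aux_correlations(selected)
  r_sel_w <- aux_correlations(selected, w)
  vars <- rownames(r_ref)
  pr <- combn(length(vars), 2)
  ia <- pr[1, ]; ib <- pr[2, ]
  rr <- r_ref[cbind(ia, ib)]
  rs <- r_sel[cbind(ia, ib)]
  rw <- r_sel_w[cbind(ia, ib)]
  data.frame(var_a = vars[ia], var_b = vars[ib],
             r_ref = rr, r_sel = rs, r_sel_w = rw,
             r_diff = abs(rr - rs),
             bias_reduction = as.numeric(bias_reduction(rr, rs, rw)),
             stringsAsFactors = FALSE)
}

#' Summarize bias reduction over auxiliary pairs
#'
#' @param report Output of [bias_report()].
#' @param r_diff_min Only pairs whose unweighted bias exceeds this value are
#'   summarized (default 0.05), mirroring the convention of flagging visibly
#'   biased pairs; pairs with undefined bias reduction are excluded.
#' @return Named vector: `median`, `mean`, `min`, `max`, `n_pairs`.
#' @export
bias_reduction_summary <- function(report, r_diff_min = 0.05) {
  keep <- report$r_diff > r_diff_min & !is.na(report$bias_reduction)
  br <- report$bias_reduction[keep]
  if (!length(br)) return(c(median = NA, mean = NA, min = NA, max = NA, n_pairs = 0))
  c(median = stats::median(br), mean = mean(br), min = min(br), max = max(br),
    n_pairs = length(br))
}

#' Train-test check of the participation weights
#'
#' Guards against overfitting of the LASSO participation model: the stacked
#' cohort is split into k folds (default 5, i.e. an 80:20 train-test ratio),
#' the model is refit on each training portion and probabilities are
#' predicted for the held-out rows, so every selected individual receives
#' exactly one out-of-sample probability. Bias-reduction summaries from the
#' out-of-sample weights are then compared with the full-sample fit.
#'
#' @param stacked Stacked cohort (selected + reference) with `participation`
#'   and `design_weight` columns.
#' @param k Number of outer folds (default 5 for an 80:20 split).
#' @param n_folds Inner cross-validation folds for each LASSO fit.
#' @param seed Integer seed (fold assignment and inner CV).
#' @param r_diff_min Pair-inclusion threshold for the summaries.
#' @return List with `full` and `out_of_sample` bias-reduction summaries,
#'   the per-pair reports, and the out-of-sample probabilities.
#' @export
crossvalidate_weights <- function(stacked, k = 5L, n_folds = 5L, seed = 1L,
                                  r_diff_min = 0.05) {
  lab <- stacked$participation
  X <- build_design(stacked)
  dw <- stacked$design_weight %||% rep(1, nrow(stacked))
  # stratified fold assignment so both classes appear in every training split
  fold <- integer(length(lab))
  fold[lab == 1L] <- local_seeded(seed, sample(rep_len(seq_len(k), sum(lab == 1L))))
  fold[lab == 0L] <- local_seeded(seed + 1L, sample(rep_len(seq_len(k), sum(lab == 0L))))
  for (f in seq_len(k)) {
    if (length(unique(lab[fold != f])) < 2L) stop_ipw("degenerate train-test split")
  }
  P_oos <- rep(NA_real_, length(lab))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit_f <- fit_participation_model(X[tr, , drop = FALSE], lab[tr],
                                     reference_design_weights = dw[tr & lab == 0L],
                                     n_folds = n_folds, seed = seed + 10L + f)
    P_oos[!tr] <- predict_participation(fit_f, X[!tr, , drop = FALSE])
  }
  fit_full <- fit_participation_model(X, lab, reference_design_weights = dw[lab == 0L],
                                      n_folds = n_folds, seed = seed)
  selected <- stacked[lab == 1L, , drop = FALSE]
  reference <- stacked[lab == 0L, , drop = FALSE]
  w_full <- compute_weights(fit_full$P)
  w_oos <- compute_weights(P_oos[lab == 1L])
  rep_full <- bias_report(reference, selected, w_full$w)
  rep_oos <- bias_report(reference, selected, w_oos$w)
  list(full = bias_reduction_summary(rep_full, r_diff_min),
       out_of_sample = bias_reduction_summary(rep_oos, r_diff_min),
       report_full = rep_full, report_out_of_sample = rep_oos,
       P_out_of_sample = P_oos[lab == 1L], fit = fit_full)
}

# HC0 sandwich variance for a weighted logistic (quasibinomial) glm fit.
robust_vcov_glm <- function(fit) {
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  pw <- fit$prior.weights
  y <- fit$y
  sc <- X * (pw * (y - mu))
  bread <- solve(crossprod(X * sqrt(pw * mu * (1 - mu))))
  bread %*% crossprod(sc) %*% bread
}

#' Univariate balance check of the weights by weighted logistic regression
#'
#' For each auxiliary variable, fits a univariate logistic regression of the
#' participation label (selected = 1, reference = 0) on the standardized
#' numeric coding of the variable, before weighting (selected rows weight 1)
#' and after weighting (selected rows carry the normalized probability
#' weights, reference rows their design weights). Well-calibrated weights
#' drive the post-weighting coefficients towards zero. Standard errors are
#' heteroskedasticity-robust (HC0 sandwich).
#'
#' @param stacked Stacked cohort with `participation` and `design_weight`.
#' @param w Probability weights for the selected rows (vector or
#'   `probability_weights`).
#' @return Data frame with one row per auxiliary variable: `beta_pre`,
#'   `se_pre`, `beta_post`, `se_post`, `flagged` (separation or non-finite
#'   fit).
#' @export
weighted_logistic_check <- function(stacked, w) {
  if (inherits(w, "probability_weights")) w <- w$w_in else w <- w / mean(w)
  lab <- stacked$participation
  if (length(w) != sum(lab == 1L))
    stop_ipw("w must have one entry per selected row")
  dw <- stacked$design_weight %||% rep(1, nrow(stacked))
  z <- aux_numeric(stacked)
  w_pre <- ifelse(lab == 1L, 1, dw)
  w_post <- w_pre
  w_post[lab == 1L] <- w
  out <- lapply(colnames(z), function(v) {
    x <- as.numeric(scale(z[, v]))
    one <- function(ow) {
      fit <- suppressWarnings(glm(lab ~ x, family = quasibinomial(), weights = ow))
      se <- sqrt(diag(robust_vcov_glm(fit)))[2]
      flag <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
        any(fit$fitted.values < 1e-8) || abs(coef(fit)[2]) > 15
      c(beta = unname(coef(fit)[2]), se = unname(se), flag = flag)
    }
    pre <- one(w_pre); post <- one(w_post)
    data.frame(variable = v, beta_pre = pre[["beta"]], se_pre = pre[["se"]],
               beta_post = post[["beta"]], se_post = post[["se"]],
               flagged = as.logical(pre[["flag"]] || post[["flag"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
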