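# Replicate simulation studies quantifying what weighting buys. These are
# the package's own evaluation experiments: each builds its inputs from the
# synthetic-cohort generator with known ground truth, runs the estimator
# under study, and returns the measured quantities.

# Calibrate a logistic intercept so the mean selection probability hits f.
calibrate_intercept <- function(lp, f) {
  uniroot(function(a) mean(plogis(a + lp)) - f, c(-40, 40), tol = 1e-10)$root
}

#' Replicate study: collider bias of SNP effects and its correction
#'
#' In each replicate a population is simulated with a polygenic trait whose
#' value drives participation (a collider between genotype and phenotype);
#' the selected sample is scanned with and without oracle probability
#' weights `(1 - P)/P` and the mean estimated effect across causal SNPs is
#' compared with the generating effect. With rare, moderate selection —
#' the regime `(1 - P)/P` weighting is designed for, where the
#' non-participant population the weights reproduce coincides with the
#' target population — the weighted estimator is unbiased while the
#' unweighted one is attenuated.
#'
#' @param n_reps Number of replicates.
#' @param n_population Population size per replicate.
#' @param n_snps Causal SNPs per replicate (all carry `beta_true`).
#' @param beta_true Per-dosage effect of each causal SNP.
#' @param h2 Trait heritability.
#' @param target_fraction Participation rate.
#' @param selection_strength Logit coefficient on the standardized trait.
#' @param seed Integer seed.
#' @return List with `bias_unweighted`, `bias_weighted` (mean deviation of
#'   the estimated from the generating effect), their Monte-Carlo standard
#'   errors, and the per-replicate means.
#' @export
scan_bias_study <- function(n_reps = 200, n_population = 40000, n_snps = 40,
                            beta_true = 0.15, h2 = 0.4,
                            target_fraction = 0.015,
                            selection_strength = 1.2, seed = 1L) {
  res <- vapply(seq_len(n_reps), function(r) {
    s <- seed * 1000L + r
    g <- simulate_genotypes(population_config(n_population, n_snps,
                                              maf_range = c(0.2, 0.5), seed = s))
    y <- simulate_phenotype(g, trait_model(rep(beta_true, n_snps), h2),
                            seed = s + 500000L)
    z <- as.numeric(scale(y))
    a <- calibrate_intercept(selection_strength * z, target_fraction)
    P <- plogis(a + selection_strength * z)
    sel <- which(local_seeded(s + 900000L,
                              rbinom(n_population, 1L, P)) == 1L)
    gs <- g
    gs$dosages <- g$dosages[sel, , drop = FALSE]
    w <- (1 - P[sel]) / P[sel]
    c(mean(run_scan(gs, y[sel])$BETA),
      mean(run_scan(gs, y[sel], weights = w)$BETA))
  }, numeric(2))
  list(bias_unweighted = mean(res[1, ]) - beta_true,
       bias_weighted = mean(res[2, ]) - beta_true,
       mc_se_unweighted = sd(res[1, ]) / sqrt(n_reps),
       mc_se_weighted = sd(res[2, ]) / sqrt(n_reps),
       beta_true = beta_true, reps = t(res))
}

#' Null calibration of the weighted scan
#'
#' Scans many null SNPs (independent of both the phenotype and the
#' participation mechanism) with informative oracle weights and reports the
#' empirical type-I error of the sandwich-variance test at a given level.
#'
#' @param n_population Population size.
#' @param n_snps Number of null SNP replicates.
#' @param target_fraction,selection_strength Participation mechanism (on an
#'   independent trait).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return List with `type1`, the number of SNPs, the effective sample size
#'   and the binomial 99% bounds around `alpha`.
#' @export
null_calibration_study <- function(n_population = 30000, n_snps = 10000,
                                   target_fraction = 0.1,
                                   selection_strength = 0.7,
                                   alpha = 0.05, seed = 1L) {
  g <- simulate_genotypes(population_config(n_population, n_snps,
                                            maf_range = c(0.05, 0.5),
                                            seed = seed))
  y_sel <- local_seeded(seed + 1L, rnorm(n_population))  # drives selection
  y_scan <- local_seeded(seed + 2L, rnorm(n_population)) # scanned, pure noise
  a <- calibrate_intercept(selection_strength * y_sel, target_fraction)
  P <- plogis(a + selection_strength * y_sel)
  sel <- which(local_seeded(seed + 3L, rbinom(n_population, 1L, P)) == 1L)
  gs <- g
  gs$dosages <- g$dosages[sel, , drop = FALSE]
  w <- (1 - P[sel]) / P[sel]
  ss <- run_scan(gs, y_scan[sel], weights = w)
  half <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / n_snps)
  list(type1 = mean(ss$P < alpha), n_snps = n_snps,
       n_selected = length(sel), n_effective = effective_sample_size(w),
       bounds = c(alpha - half, alpha + half))
}

#' Weight-recovery study on the default collider scenario
#'
#' Simulates the default healthy-volunteer scenario, constructs oracle
#' weights from the true participation probabilities and LASSO weights from
#' the fitted participation model, and measures (a) how far oracle-weighted
#' means of the 14 auxiliaries sit from the population means in Monte-Carlo
#' standard-error units and (b) the bias-reduction summaries over auxiliary
#' pairs.
#'
#' @param config A [scenario_config()]; genotypes are irrelevant here, so a
#'   small `n_snps` keeps it cheap.
#' @param seed Integer seed (scenario and LASSO).
#' @return List with `mean_z` (per-variable standardized deviations under
#'   oracle weights), `summary_oracle`, `summary_lasso`, the per-pair
#'   reports and the fitted weights.
#' @export
weight_recovery_study <- function(config = NULL, seed = 1L) {
  config <- config %||% scenario_config(n_snps = 50L, seed = seed)
  sim <- simulate_scenario(config)
  sel <- sim$selected
  w_oracle <- (1 - sel$true_P) / sel$true_P
  z_pop <- aux_numeric(sim$population)
  z_sel <- aux_numeric(sel)
  mean_z <- vapply(seq_len(ncol(z_pop)), function(j) {
    (weighted_moments(z_sel[, j], w_oracle) - mean(z_pop[, j])) /
      weighted_mean_se(z_sel[, j], w_oracle)
  }, numeric(1))
  names(mean_z) <- colnames(z_pop)
  X <- build_design(sim$stacked)
  fit <- fit_participation_model(X, sim$stacked$participation,
                                 reference_design_weights = sim$reference$design_weight,
                                 seed = seed + 7L)
  pw <- compute_weights(fit$P)
  report_oracle <- bias_report(sim$reference, sel, w_oracle)
  report_lasso <- bias_report(sim$reference, sel, pw$w)
  list(mean_z = mean_z,
       summary_oracle = bias_reduction_summary(report_oracle),
       summary_lasso = bias_reduction_summary(report_lasso),
       report_oracle = report_oracle, report_lasso = report_lasso,
       weights = pw, fit = fit, simulation = sim)
}

#' LD-score regression recovery study
#'
#' Draws association Z-scores from the polygenic model
#' `Z_j ~ N(0, sqrt(1 + n h2 l_j / M))` over synthetic LD scores and checks
#' that the regression recovers the generating heritability with an
#' intercept of 1.
#'
#' @param h2 Generating heritability.
#' @param n GWAS sample size.
#' @param M Number of SNPs.
#' @param n_blocks Jackknife blocks.
#' @param seed Integer seed.
#' @return The `ldsc_fit`, plus the generating values as attributes.
#' @export
ldsc_recovery_study <- function(h2 = 0.2, n = 20000, M = 5000,
                                n_blocks = 200L, seed = 1L) {
  local_seeded(seed, {
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("rs%06d", seq_len(M)), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    z <- rnorm(M, 0, sqrt(1 + n * h2 * l2 / M))
    fit <- estimate_h2(data.frame(SNP = ld$SNP, Z = z, N = n), ld,
                       n_blocks = n_blocks)
    attr(fit, "h2_true") <- h2
    fit
  })
}

#' MR selection-correction study
#'
#' Replicates an instrument panel whose observed exposure effects carry
#' estimation noise (variance a stated fraction of the spread of the true
#' effects, emulating instruments significant in only one scan arm) and
#' compares the bias of the uncorrected and corrected IVW estimates of a
#' known causal effect.
#'
#' @param n_reps Replicates.
#' @param m Instruments per replicate.
#' @param alpha_true Generating causal effect.
#' @param noise_fraction Exposure-noise variance as a fraction of the
#'   exposure-effect variance (default 0.25).
#' @param seed Integer seed.
#' @return List with mean uncorrected and corrected estimates, their biases
#'   and Monte-Carlo standard errors.
#' @export
mr_correction_study <- function(n_reps = 500, m = 30, alpha_true = 0.3,
                                noise_fraction = 0.25, seed = 1L) {
  local_seeded(seed, {
    tau <- 0.06
    se_exp <- sqrt(noise_fraction) * tau
    res <- replicate(n_reps, {
      b_true <- rnorm(m, 0, tau)
      b_obs <- b_true + rnorm(m, 0, se_exp)
      se_out <- runif(m, 0.015, 0.03)
      b_out <- alpha_true * b_true + rnorm(m, 0, se_out)
      ins <- data.frame(snp = sprintf("s%d", seq_len(m)),
                        beta_exp = b_obs, se_exp = se_exp,
                        beta_out = b_out, se_out = se_out)
      fit <- suppressWarnings(corrected_ivw(ivw(ins)))
      c(fit$alpha, fit$alpha_corrected)
    })
    list(alpha_true = alpha_true,
         mean_uncorrected = mean(res[1, ]),
         mean_corrected = mean(res[2, ]),
         bias_uncorrected = mean(res[1, ]) - alpha_true,
         bias_corrected = mean(res[2, ]) - alpha_true,
         mc_se = apply(res, 1, sd) / sqrt(n_reps))
  })
}

#' Calibration of the paired difference tests under the null
#'
#' Simulates paired weighted/unweighted estimates with equal truth and
#' overlapping data (shared polygenic signal, arm-specific noise) for the
#' three comparison statistics — heritability differences, genetic-
#' correlation differences and MR-estimate differences — and reports the
#' empirical type-I error of each jackknife-correlation difference test.
#'
#' @param n_reps Replicates per statistic.
#' @param M SNPs for the LD-score statistics.
#' @param m Instruments for the MR statistic.
#' @param level Test level (default 0.05).
#' @param seed Integer seed.
#' @return List with `type1` (named vector over `h2`, `rg`, `alpha`),
#'   `sd_z`, and the binomial 99% bounds.
#' @export
difference_calibration_study <- function(n_reps = 500, M = 2000, m = 50,
                                         level = 0.05, seed = 1L) {
  n <- 20000
  z_h2 <- local_seeded(seed, {
    h2 <- 0.2
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("s%d", seq_len(M)), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    replicate(n_reps, {
      u <- rnorm(M, 0, sqrt(n * h2 * l2 / M))
      fa <- estimate_h2(data.frame(SNP = ld$SNP, Z = u + rnorm(M), N = n), ld)
      fb <- estimate_h2(data.frame(SNP = ld$SNP, Z = u + rnorm(M), N = n), ld)
      r <- jackknife_correlation(fa$loo_h2, fb$loo_h2)
      difference_test(fa$h2, fb$h2, fa$h2_se, fb$h2_se, r)$Z
    })
  })
  z_rg <- local_seeded(seed + 1L, {
    h1 <- 0.3; h2t <- 0.25; rg <- 0.5
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("s%d", seq_len(M)), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    v1 <- n * h1 * l2 / M; v2 <- n * h2t * l2 / M
    replicate(n_reps, {
      u1 <- rnorm(M, 0, sqrt(v1))
      u2 <- rg * sqrt(v2 / v1) * u1 + rnorm(M, 0, sqrt((1 - rg^2) * v2))
      arm <- function() list(
        s1 = data.frame(SNP = ld$SNP, A1 = "A", A2 = "G", Z = u1 + rnorm(M), N = n),
        s2 = data.frame(SNP = ld$SNP, A1 = "A", A2 = "G", Z = u2 + rnorm(M), N = n))
      a <- arm(); b <- arm()
      fa <- estimate_rg(a$s1, a$s2, ld)
      fb <- estimate_rg(b$s1, b$s2, ld)
      r <- jackknife_correlation(fa$loo_rg, fb$loo_rg)
      difference_test(fa$rg, fb$rg, fa$rg_se, fb$rg_se, r)$Z
    })
  })
  z_mr <- local_seeded(seed + 2L, {
    replicate(n_reps, {
      b <- rnorm(m, 0, 0.08)
      arm <- function() {
        se_out <- runif(m, 0.015, 0.03)
        data.frame(snp = sprintf("s%d", seq_len(m)), beta_exp = b, se_exp = 0,
                   beta_out = 0.3 * b + rnorm(m, 0, se_out), se_out = se_out)
      }
      mr_difference(arm(), arm())$test$Z
    })
  })
  crit <- qnorm(1 - level / 2)
  half <- qnorm(0.995) * sqrt(level * (1 - level) / n_reps)
  list(type1 = c(h2 = mean(abs(z_h2) > crit), rg = mean(abs(z_rg) > crit),
                 alpha = mean(abs(z_mr) > crit)),
       sd_z = c(h2 = sd(z_h2), rg = sd(z_rg), alpha = sd(z_mr)),
       bounds = c(level - half, level + half))
}

#' Sex-differential participation study
#'
#' Simulates sex-differential volunteering: participation depends on a
#' heritable trait with opposite sign in males and females, so autosomal
#' variants of the trait become associated with sex in the selected sample.
#' The study runs paired unweighted and oracle-weighted scans of sex and
#' estimates the apparent autosomal "heritability" of sex in each arm by
#' LD-score regression; weighting should attenuate it.
#'
#' @param n_reps Replicates (estimates are averaged).
#' @param n_population Population size per replicate.
#' @param n_snps Panel size (LD blocks give the score variation the
#'   regression needs).
#' @param h2_trait Heritability of the participation-driving trait.
#' @param selection_strength Logit coefficient on the standardized trait
#'   (sign flipped between sexes).
#' @param target_fraction Participation rate.
#' @param seed Integer seed.
#' @return List with mean `h2_unweighted`, `h2_weighted` and per-replicate
#'   values.
#' @export
sex_participation_study <- function(n_reps = 3, n_population = 25000,
                                    n_snps = 800, h2_trait = 0.6,
                                    selection_strength = 1.5,
                                    target_fraction = 0.25, seed = 1L) {
  res <- vapply(seq_len(n_reps), function(r) {
    s <- seed * 100L + r * 10L
    g <- simulate_genotypes(population_config(
      n_population, n_snps, maf_range = c(0.1, 0.5),
      ld_block_size = 4L, ld_rho = c(0.2, 0.8), seed = s))
    y <- simulate_phenotype(g, trait_model(
      local_seeded(s + 1L, rnorm(n_snps) * 0.05), h2_trait), seed = s + 2L)
    sex <- local_seeded(s + 3L, rbinom(n_population, 1L, 0.5))
    zy <- as.numeric(scale(y))
    lp <- selection_strength * zy * (2 * sex - 1)
    a <- calibrate_intercept(lp, target_fraction)
    P <- plogis(a + lp)
    sel <- which(local_seeded(s + 4L, rbinom(n_population, 1L, P)) == 1L)
    gs <- g
    gs$dosages <- g$dosages[sel, , drop = FALSE]
    w <- (1 - P[sel]) / P[sel]
    sc <- sex_scan(gs, sex[sel], weights = w)
    ld <- compute_ld_scores(gs, window_kb = 100)
    hu <- estimate_h2(sc$unweighted, ld, n_blocks = 100L)
    hw <- estimate_h2(sc$weighted, ld, n_blocks = 100L)
    c(hu$h2, hw$h2)
  }, numeric(2))
  list(h2_unweighted = mean(res[1, ]), h2_weighted = mean(res[2, ]),
       reps = t(res))
}
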