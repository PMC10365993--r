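test_that("LD scores reflect the panel's correlation structure", {
  # independent SNPs: scores near 1
  g1 <- simulate_genotypes(population_config(3000, 60, ld_block_size = 1,
                                             seed = 1))
  ld1 <- compute_ld_scores(g1, window_kb = 500)
  expect_within(mean(ld1$L2), 1, 0.05)
  # a duplicated SNP doubles its score
  g2 <- g1
  g2$dosages[, 2] <- g2$dosages[, 1]
  ld2 <- compute_ld_scores(g2, window_kb = 500)
  expect_within(ld2$L2[1], ld1$L2[1] + 1, 0.05)
  # constructed block: 5 SNPs with pairwise r^2 = 0.25 gives l ~ 2
  rho <- sqrt(0.5)  # haplotype-latent correlation giving dosage r ~ 0.5
  g3 <- simulate_genotypes(population_config(8000, 5, ld_block_size = 5,
                                             ld_rho = rho^2,
                                             maf_range = c(0.5, 0.5), seed = 3))
  r2_real <- mean(cor(g3$dosages)[upper.tri(diag(5))]^2)
  ld3 <- compute_ld_scores(g3, window_kb = 500)
  expect_within(mean(ld3$L2), 1 + 4 * r2_real, 0.1)
})

test_that("heritability regression recovers truth, null and inflation behaviour", {
  fit <- ldsc_recovery_study(h2 = 0.2, n = 20000, M = 4000, seed = 5)
  expect_within(fit$h2, 0.2, 2 * fit$h2_se)
  expect_within(fit$intercept, 1, 2 * fit$intercept_se)
  # null: slope within noise of zero
  fit0 <- ldsc_recovery_study(h2 = 0, n = 20000, M = 4000, seed = 6)
  expect_within(fit0$h2, 0, 2 * fit0$h2_se)
  expect_within(fit0$intercept, 1, 2 * fit0$intercept_se)
  # additive chi-square inflation moves the intercept, not the slope
  withr::with_seed(7, {
    M <- 4000; n <- 20000
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("s%d", 1:M), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    z <- rnorm(M, 0, sqrt(1 + n * 0.2 * l2 / M))
    f1 <- estimate_h2(data.frame(SNP = ld$SNP, Z = z, N = n), ld)
    z_infl <- sign(z) * sqrt(z^2 + 0.5)
    f2 <- estimate_h2(data.frame(SNP = ld$SNP, Z = z_infl, N = n), ld)
    expect_within(f2$intercept - f1$intercept, 0.5, 0.02)
    expect_within(f2$h2, f1$h2, 2 * f1$h2_se)
  })
  # jackknife SE close to the analytic weighted-regression SE
  withr::with_seed(8, {
    M <- 4000; n <- 20000
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("s%d", 1:M), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    z <- rnorm(M, 0, sqrt(1 + n * 0.2 * l2 / M))
    fit <- estimate_h2(data.frame(SNP = ld$SNP, Z = z, N = n), ld)
    wfit <- lm(z^2 ~ I(n * l2 / M), weights = 1 / pmax(l2, 1))
    se_analytic <- summary(wfit)$coefficients[2, 2]
    expect_lt(fit$h2_se / se_analytic, 1.5)
    expect_gt(fit$h2_se / se_analytic, 1 / 1.5)
  })
})

test_that("genetic correlation is exact for self, null for independence, recovered for rg = 0.5", {
  withr::with_seed(11, {
    M <- 3000; n <- 20000
    l2 <- runif(M, 1, 4)
    ld <- structure(data.frame(SNP = sprintf("s%d", 1:M), L2 = l2),
                    M = M, n = n, class = c("ld_scores", "data.frame"))
    v <- n * 0.3 * l2 / M
    u <- rnorm(M, 0, sqrt(v))
    ss1 <- data.frame(SNP = ld$SNP, A1 = "A", A2 = "G", Z = u + rnorm(M), N = n)
    # self-correlation
    self <- estimate_rg(ss1, ss1, ld)
    expect_equal(self$rg, 1, tolerance = 1e-10)
    # independent traits
    ss_ind <- data.frame(SNP = ld$SNP, A1 = "A", A2 = "G",
                         Z = rnorm(M, 0, sqrt(1 + v)), N = n)
    ind <- estimate_rg(ss1, ss_ind, ld)
    expect_within(ind$rg, 0, 2 * ind$rg_se)
    # rg = 0.5 recovery
    u2 <- 0.5 * u + rnorm(M, 0, sqrt(0.75 * v))
    ss2 <- data.frame(SNP = ld$SNP, A1 = "A", A2 = "G", Z = u2 + rnorm(M), N = n)
    rec <- estimate_rg(ss1, ss2, ld)
    expect_within(rec$rg, 0.5, 2 * rec$rg_se)
    # allele harmonization: swapping alleles flips Z and leaves rg unchanged
    ss2_fl <- ss2
    ss2_fl$A1 <- "G"; ss2_fl$A2 <- "A"; ss2_fl$Z <- -ss2_fl$Z
    expect_equal(estimate_rg(ss1, ss2_fl, ld)$rg, rec$rg, tolerance = 1e-12)
    ss2_bad <- ss2
    ss2_bad$A1 <- "T"
    expect_error(estimate_rg(ss1, ss2_bad, ld), "allele")
  })
})

test_that("liability conversion matches its closed forms", {
  expect_equal(liability_conversion(0, 0.3, 0.2), 0)
  expect_equal(liability_conversion(1, 0.5, 0.5), pi / 2, tolerance = 1e-12)
  # K = 0.5, z = dnorm(0): multiplier K(1-K)/z^2 = 0.25 * 2 * pi
  expect_equal(ipwgwas:::liability_multiplier(0.5, 0.5), 0.25 * 2 * pi)
  expect_error(liability_conversion(0.1, 0, 0.5), "K")
})

test_that("jackknife correlation handles identity, negation and independence", {
  a <- withr::with_seed(21, rnorm(200))
  expect_equal(jackknife_correlation(a, a), 1)
  expect_equal(jackknife_correlation(a, -a), -1)
  b <- withr::with_seed(22, rnorm(200))
  expect_lt(abs(jackknife_correlation(a, b)), 0.25)  # ~3.5 sd of a null cor
  expect_warning(r0 <- jackknife_correlation(a, rep(1, 200)), "zero variance")
  expect_equal(r0, 0)
  expect_error(jackknife_correlation(a, b[1:10]), "equal length")
})

test_that("the paired difference test reproduces its arithmetic and degenerate cases", {
  t1 <- difference_test(0.5, 0.5, 0.05, 0.04, 0.3)
  expect_equal(t1$Z, 0)
  t2 <- difference_test(0.1, 0.2, 0.05, 0.05, 0)
  expect_equal(t2$se_diff, sqrt(2) * 0.05)
  t3 <- difference_test(0.3, 0.1, 0.05, 0.05, 0.5)
  expect_equal(t3$se_diff, 0.05)
  expect_equal(t3$Z, 4)
  expect_equal(t3$P, 2 * pnorm(-4), tolerance = 1e-12)
  # identical arms with r = 1: zero difference, Z defined as 0
  t4 <- difference_test(0.2, 0.2, 0.05, 0.05, 1)
  expect_equal(t4$Z, 0)
  # inconsistent inputs: nonzero difference with zero variance
  expect_error(difference_test(0.3, 0.1, 0.05, 0.05, 1), "inconsistent")
  expect_error(difference_test(0.3, 0.1, 0.05, 0.05, 1.4), "\\[-1, 1\\]")
})

test_that("equal weights give identical weighted and unweighted heritability pipelines", {
  n <- 1200
  g <- simulate_genotypes(population_config(n, 200, ld_block_size = 4,
                                            ld_rho = c(0.2, 0.8), seed = 31))
  eff <- withr::with_seed(32, rnorm(200) * 0.08)
  y <- simulate_phenotype(g, trait_model(eff, 0.4), seed = 33)
  cfg <- gwas_config(robust_unweighted = TRUE)
  ss <- run_scan(g, y, config = cfg)
  ssw <- run_scan(g, y, config = cfg, weights = rep(3, n))
  ld <- compute_ld_scores(g, window_kb = 100)
  fa <- estimate_h2(ss, ld, n_blocks = 50)
  fb <- estimate_h2(ssw, ld, n_blocks = 50)
  expect_equal(fa$h2, fb$h2, tolerance = 1e-9)
  r <- jackknife_correlation(fa$loo_h2, fb$loo_h2)
  expect_equal(r, 1, tolerance = 1e-9)
  expect_equal(difference_test(fa$h2, fb$h2, fa$h2_se, fb$h2_se, 1)$Z, 0)
})
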