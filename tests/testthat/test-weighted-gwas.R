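test_that("quality control removes monomorphic, low-call-rate and HWE-violating SNPs", {
  g <- simulate_genotypes(population_config(50, 4, maf_range = c(0.3, 0.4),
                                            seed = 1))
  g$dosages[, 2] <- 0L                                    # monomorphic
  g$dosages[1:8, 3] <- NA_integer_                        # 84% call rate
  g$dosages[, 4] <- rep(c(0L, 2L), 25)                    # no heterozygotes
  # HWE oracle for counts (25, 0, 25): chi-square on 1 df
  p <- 0.5
  expected <- 50 * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(25, 0, 25) - expected)^2 / expected)
  expect_lt(pchisq(stat, 1, lower.tail = FALSE), 1e-6)
  gq <- suppressWarnings(qc_filter(g))
  expect_equal(gq$snp_meta$snp, g$snp_meta$snp[1])
  rep <- attr(gq, "qc_report")
  expect_equal(rep$removed[rep$criterion == "hwe"], 1)
})

test_that("the weighted scan matches the dense matrix oracle on random instances", {
  for (s in 1:20) {
    n <- 50
    g <- simulate_genotypes(population_config(n, 1, maf_range = c(0.2, 0.5),
                                              seed = s))
    covars <- withr::with_seed(s + 100, matrix(rnorm(n * 3), n, 3))
    y <- withr::with_seed(s + 200, rnorm(n))
    w <- withr::with_seed(s + 300, rlnorm(n, 0, 0.6))
    ss <- run_scan(g, y, weights = w, covariates = covars)
    X <- cbind(g$dosages[, 1], 1, covars)
    o <- wls_sandwich_oracle(X, y, w)
    expect_lt(abs(ss$BETA[1] - o$beta[1]), 1e-10)
    expect_lt(abs(ss$SE[1] - sqrt(o$vcov[1, 1])), 1e-10)
  }
})

test_that("unit weights give OLS with classical errors, and sandwich equals HC0", {
  n <- 120
  g <- simulate_genotypes(population_config(n, 5, seed = 7))
  covars <- withr::with_seed(8, matrix(rnorm(n * 2), n, 2))
  y <- withr::with_seed(9, rnorm(n))
  ss <- run_scan(g, y, covariates = covars)
  ssw <- run_scan(g, y, weights = rep(1, n), covariates = covars)
  for (j in 1:5) {
    f <- lm(y ~ g$dosages[, j] + covars)
    expect_lt(abs(ss$BETA[j] - coef(f)[2]), 1e-12)
    expect_lt(abs(ss$SE[j] - summary(f)$coefficients[2, 2]), 1e-12)
    expect_lt(abs(ssw$BETA[j] - coef(f)[2]), 1e-12)
    if (requireNamespace("sandwich", quietly = TRUE)) {
      expect_lt(abs(ssw$SE[j]^2 - sandwich::vcovHC(f, "HC0")[2, 2]), 1e-10)
    }
  }
  # constant weights reduce the weighted arm to the robust unweighted arm
  ssc <- run_scan(g, y, weights = rep(2.5, n), covariates = covars)
  ssr <- run_scan(g, y, config = gwas_config(robust_unweighted = TRUE),
                  covariates = covars)
  expect_equal(ssc$BETA, ssr$BETA, tolerance = 1e-12)
  expect_equal(ssc$SE, ssr$SE, tolerance = 1e-10)
  expect_equal(ssc$N, ssr$N, tolerance = 1e-9)
  # exact linear outcome: zero residuals, zero sandwich variance
  y_lin <- 2 + 0.5 * g$dosages[, 1]
  ss0 <- run_scan(g, y_lin, weights = rep(1, n))
  expect_lt(ss0$SE[1], 1e-8)
  # Z/P consistency
  expect_equal(ss$P, 2 * pnorm(-abs(ss$Z)), tolerance = 1e-12)
  expect_equal(ss$Z, ss$BETA / ss$SE, tolerance = 1e-12)
})

test_that("effect standardization follows the printed formula", {
  s <- standardize_effects(1, 0.5, 99)
  expect_equal(s$beta_std, 1 / sqrt(50))
  expect_equal(s$se_std, 1 / sqrt(50))
  s0 <- standardize_effects(0, 0.3, 1000)
  expect_equal(s0$beta_std, 0)
  expect_equal(s0$se_std, 1 / sqrt(2 * 0.3 * 0.7 * 1000))
  # beta_std / se_std recovers Z for any input
  z <- c(-3.2, 0.4, 7.1)
  sv <- standardize_effects(z, c(0.1, 0.25, 0.45), c(500, 1000, 2000))
  expect_equal(sv$beta_std / sv$se_std, z, tolerance = 1e-12)
  expect_error(standardize_effects(1, 0, 100), "\\(0, 1\\)")
})

test_that("scan comparison classifies discoveries, changes and sign flips", {
  ss <- data.frame(SNP = c("a", "b", "c", "d"), BETA = c(0.10, 0.10, 0.2, 0.1),
                   P = c(1e-9, 1e-9, 0.5, 1e-9))
  ss_w <- data.frame(SNP = c("a", "b", "c", "d"), BETA = c(0.07, 0.13, 0.2, -0.1),
                     P = c(1e-9, 0.5, 1e-9, 1e-9))
  cmp <- compare_scans(ss, ss_w, threshold = 5e-8)
  tab <- cmp$table
  expect_equal(tab$discovery, c("both", "GWA-only", "wGWA-only", "both"))
  expect_equal(tab$relative_change[1], 0.3)       # reduced
  expect_equal(tab$change[1], "reduced")
  expect_equal(tab$relative_change[2], -0.3)      # increased
  expect_equal(tab$change[2], "increased")
  expect_true(tab$sign_flip[4])
  # identical arms: all both/stable, no flips
  cmp0 <- compare_scans(ss, ss, threshold = 5e-8)
  expect_true(all(cmp0$table$discovery == "both"))
  expect_true(all(cmp0$table$change == "stable"))
  expect_equal(cmp0$summary$n_sign_flips, 0)
  expect_error(compare_scans(ss, ss_w[c(2, 1, 3, 4), ], 5e-8), "different SNP")
})

test_that("clumping keeps LD-independent lead SNPs", {
  n <- 800
  g <- simulate_genotypes(population_config(n, 6, ld_block_size = 2,
                                            ld_rho = 0.95, bp_spacing = 10000,
                                            seed = 13))
  # SNPs 1-2 are in near-perfect LD and 10 kb apart; SNP 5 is >250 kb... no:
  # spacing 10 kb means all within the window; rely on r2 for separation
  ss <- data.frame(SNP = g$snp_meta$snp, CHR = g$snp_meta$chr,
                   BP = g$snp_meta$bp,
                   P = c(1e-10, 1e-9, 0.5, 0.5, 0.5, 0.5))
  leads <- clump(ss, g, window_kb = 250, r2_max = 0.1)
  expect_equal(leads, g$snp_meta$snp[1])  # partner pruned by r2
  # distant significant SNPs both survive
  g2 <- simulate_genotypes(population_config(n, 2, bp_spacing = 300000, seed = 14))
  ss2 <- data.frame(SNP = g2$snp_meta$snp, CHR = 1, BP = g2$snp_meta$bp,
                    P = c(1e-10, 1e-9))
  expect_equal(sort(clump(ss2, g2, window_kb = 250, r2_max = 0.1)),
               sort(g2$snp_meta$snp))
  # single significant SNP is its own lead
  expect_equal(clump(ss2[1, ], g2), g2$snp_meta$snp[1])
  # unsorted positions are refused
  g3 <- g2
  g3$snp_meta$bp <- rev(g3$snp_meta$bp)
  expect_error(clump(ss2, g3), "strictly increasing")
})

test_that("sex and participation-liability scans reduce to expected special cases", {
  n <- 500
  g <- simulate_genotypes(population_config(n, 10, seed = 17))
  sex <- withr::with_seed(18, rbinom(n, 1, 0.5))
  res <- sex_scan(g, sex, weights = rep(1, n), snp_list = g$snp_meta$snp[1:3])
  expect_equal(res$unweighted$BETA, res$weighted$BETA, tolerance = 1e-12)
  expect_equal(nrow(res$comparison), 3)
  # no sex-differential participation: both arms null-calibrated
  expect_gt(min(res$unweighted$P), 1e-4)
  P <- withr::with_seed(19, runif(n, 0.05, 0.6))
  liab <- participation_liability_scan(g, P, weights = (1 - P) / P)
  expect_true(attr(liab, "liability_proxy"))
  expect_error(participation_liability_scan(g, rep(0.2, n), weights = rep(1, n)),
               "constant")
})

test_that("the liability scan detects SNPs causal for the selection-driving trait", {
  n <- 4000
  g <- simulate_genotypes(population_config(n, 20, maf_range = c(0.2, 0.5),
                                            seed = 23))
  eff <- c(rep(0.4, 5), rep(0, 15))   # first five SNPs drive the trait
  y <- simulate_phenotype(g, trait_model(eff, 0.5), seed = 24)
  P <- plogis(-2 + 1.5 * as.numeric(scale(y)))
  sel <- which(withr::with_seed(25, rbinom(n, 1, P)) == 1)
  gs <- g
  gs$dosages <- g$dosages[sel, , drop = FALSE]
  ss <- participation_liability_scan(gs, P[sel], weights = (1 - P[sel]) / P[sel])
  expect_true(all(abs(ss$Z[1:5]) > 3))     # causal SNPs surface
  expect_lt(mean(abs(ss$Z[6:20]) > 3), 0.2) # null SNPs mostly quiet
})
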