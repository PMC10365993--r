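test_that("simulated genotypes follow Hardy-Weinberg proportions with the right moments", {
  g <- simulate_genotypes(population_config(50000, 30, maf_range = c(0.1, 0.4),
                                            seed = 11))
  p <- g$snp_meta$freq
  expect_true(all(p > 0 & p < 1))
  expect_equal(g$snp_meta$freq, colMeans(g$dosages) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  # dosage variance against the binomial(2, p) oracle, within 3 SEs
  for (j in c(1, 10, 30)) {
    d <- g$dosages[, j]
    pj <- mean(d) / 2
    v_oracle <- 2 * pj * (1 - pj)
    # SE of the sample variance from the binomial fourth moment
    mu <- 2 * pj
    m4 <- (0 - mu)^4 * (1 - pj)^2 + (1 - mu)^4 * 2 * pj * (1 - pj) +
      (2 - mu)^4 * pj^2
    se_var <- sqrt((m4 - v_oracle^2) / length(d))
    expect_within(var(d), v_oracle, 3 * se_var)
  }
  # HWE chi-square pass rate
  hp <- ipwgwas:::hwe_chisq_p(colSums(g$dosages == 0), colSums(g$dosages == 1),
                              colSums(g$dosages == 2))
  expect_true(all(hp > 1e-6))
})

test_that("genotype panel symmetry, independence and LD structure behave as designed", {
  g0 <- simulate_genotypes(population_config(20000, 20,
                                             maf_range = c(0.5, 0.5), seed = 2))
  expect_within(mean(colMeans(g0$dosages)), 1, 0.02)
  # independent SNPs: adjacent correlations near zero
  g1 <- simulate_genotypes(population_config(5000, 40, ld_block_size = 1,
                                             seed = 3))
  r_adj <- sapply(1:39, function(j) cor(g1$dosages[, j], g1$dosages[, j + 1]))
  expect_lt(mean(abs(r_adj)), 0.02)
  # block LD: within-block r clearly above cross-block r
  g2 <- simulate_genotypes(population_config(5000, 40, ld_block_size = 5,
                                             ld_rho = 0.6, seed = 4))
  r_within <- cor(g2$dosages[, 1], g2$dosages[, 2])
  r_cross <- cor(g2$dosages[, 5], g2$dosages[, 6])
  expect_gt(r_within, 0.2)
  expect_lt(abs(r_cross), 0.05)
  expect_error(population_config(0, 10), "positive")
  expect_error(population_config(10, 10, maf_range = c(0, 0.5)), "maf_range")
})

test_that("phenotype simulation hits the target heritability and prevalence", {
  g <- simulate_genotypes(population_config(20000, 200, seed = 5))
  eff <- withr::with_seed(6, rnorm(200) * rbinom(200, 1, 0.5))
  y <- simulate_phenotype(g, trait_model(eff, 0.5), seed = 7)
  gv <- as.numeric(scale(g$dosages, scale = FALSE) %*% eff)
  expect_within(var(gv) / var(y), 0.5, 0.03)
  # no heritability: no SNP signal
  y0 <- simulate_phenotype(g, trait_model(eff, 0), seed = 8)
  j <- which.max(abs(eff))
  b <- coef(lm(y0 ~ g$dosages[, j]))[2]
  expect_lt(abs(b), 3 * sqrt(var(y0) / (var(g$dosages[, j]) * 20000)))
  # binary: median threshold gives half cases
  yb <- simulate_phenotype(g, trait_model(eff, 0.5, prevalence = 0.5), seed = 9)
  expect_within(mean(yb), 0.5, 0.01)
  expect_error(trait_model(eff, 1.2), "h2_target")
})

test_that("auxiliary variables carry the declared level structure and loadings", {
  tc <- make_toy_cohort(4000, seed = 21)
  spec <- aux_spec()
  cats <- spec$variable[spec$type == "categorical"]
  expect_equal(unname(vapply(tc$cohort[cats], nlevels, integer(1))),
               c(7L, 2L, 6L, 3L, 4L, 5L, 4L, 3L, 3L))
  # positive loading induces positive correlation with the trait
  expect_gt(cor(tc$cohort$education, tc$trait), 0.4)
  # zero loadings: independence
  aux0 <- simulate_auxiliary(cbind(tc$trait), loadings = NULL, seed = 22)
  expect_lt(abs(cor(aux0$age, tc$trait)), 0.05)
  expect_error(simulate_auxiliary(cbind(tc$trait),
                                  matrix(1, 1, 1, dimnames = list("nope", NULL))),
               "unknown auxiliary")
})

test_that("participation selects at the target rate and shifts selected means", {
  tc <- make_toy_cohort(60000, seed = 31)
  # the emulated cohort's participation rate of 5.5%
  coh <- apply_participation(tc$cohort, participation_model(target_fraction = 0.055),
                             seed = 32)
  expect_within(mean(coh$participation), 0.055, 0.003)
  expect_within(mean(coh$true_P), 0.055, 1e-6)
  # selection on education raises the selected sample's education mean
  coh2 <- apply_participation(tc$cohort,
                              participation_model(c(education = 1),
                                                  target_fraction = 0.1),
                              seed = 33)
  expect_gt(mean(coh2$education[coh2$participation == 1]),
            mean(coh2$education) + 0.3 * sd(coh2$education))
  # constant probability: weighted and unweighted means agree
  w <- (1 - coh$true_P) / coh$true_P
  sel <- coh$participation == 1
  expect_equal(weighted_moments(coh$age[sel], rep(1, sum(sel))),
               mean(coh$age[sel]))
  # interaction coefficient distorts the pair correlation among the selected
  coh3 <- apply_participation(tc$cohort,
                              participation_model(c("age:bmi" = 0.5),
                                                  target_fraction = 0.1),
                              seed = 34)
  s3 <- coh3$participation == 1
  expect_gt(cor(coh3$age[s3], coh3$bmi[s3]),
            cor(coh3$age, coh3$bmi) + 0.2)
})

test_that("oracle weights recover population means of the auxiliaries", {
  tc <- make_toy_cohort(50000, seed = 41)
  coh <- apply_participation(
    tc$cohort,
    participation_model(c(education = 0.3, "education:age" = 0.4),
                        target_fraction = 0.1),
    seed = 42)
  sel <- coh[coh$participation == 1, ]
  w <- (1 - sel$true_P) / sel$true_P
  z_pop <- ipwgwas:::aux_numeric(coh)
  z_sel <- ipwgwas:::aux_numeric(sel)
  for (v in c("education", "age", "smoking")) {
    m <- weighted_moments(z_sel[, v], w)
    se <- ipwgwas:::weighted_mean_se(z_sel[, v], w)
    expect_within(m, mean(z_pop[, v]), 3 * se)
  }
})

test_that("reference sampling supports simple and stratified designs", {
  tc <- make_toy_cohort(20000, seed = 51)
  tc$cohort$participation <- 0L
  ref <- draw_reference_sample(tc$cohort, 1000, seed = 52)
  expect_equal(nrow(ref), 1000)
  expect_true(all(ref$design_weight == 1))
  # stratified: sampling one sex at half rate doubles its design weight
  ref2 <- draw_reference_sample(
    tc$cohort, 1000,
    design_scheme = list(by = "sex", rates = c(male = 1, female = 0.5)),
    seed = 53)
  wm <- unique(ref2$design_weight[ref2$sex == "male"])
  wf <- unique(ref2$design_weight[ref2$sex == "female"])
  expect_within(wf / wm, 2, 0.1)
  # Horvitz-Thompson: design-weighted means recover the population mean
  expect_within(ht_mean(ref2$education, ref2$design_weight),
                mean(tc$cohort$education),
                3 * sd(tc$cohort$education) / sqrt(600))
  expect_error(draw_reference_sample(tc$cohort, 0), "positive")
})

test_that("identical seeds reproduce the whole scenario byte for byte", {
  cfg <- scenario_config(n_population = 1500, n_snps = 40, n_reference = 300,
                         seed = 61)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$reference, s2$reference)
})
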