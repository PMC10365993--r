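#' LD scores of a genotype panel
#'
#' The LD score of SNP j is the sum of its squared correlations with every
#' SNP within a physical window (itself included), each adjusted for
#' finite-sample bias by `r2 - (1 - r2) / (n - 2)`. Under a polygenic
#' architecture the expected association chi-square grows linearly in the LD
#' score, which is what LD-score regression exploits.
#'
#' @param g A (QC-filtered) `genotype_set`.
#' @param window_kb Window half-width in kilobases (default 1000).
#' @return An `ld_scores` data frame with columns `SNP` and `L2`, attributes
#'   `M` (number of SNPs) and `n` (panel size).
#' @export
compute_ld_scores <- function(g, window_kb = 1000) {
  d <- g$dosages
  n <- nrow(d); m <- ncol(d)
  S <- scale(d)
  S[is.na(S) | is.nan(S)] <- 0
  meta <- g$snp_meta
  l2 <- numeric(m)
  win <- window_kb * 1000
  # chunked cross-products: SNPs are in genomic order within chromosomes
  for (ch in unique(meta$chr)) {
    idx <- which(meta$chr == ch)
    bp <- meta$bp[idx]
    chunk <- 256L
    for (s0 in seq(1L, length(idx), by = chunk)) {
      ci <- idx[s0:min(s0 + chunk - 1L, length(idx))]
      lo <- findInterval(meta$bp[ci[1]] - win - 1, bp) + 1L
      hi <- findInterval(meta$bp[ci[length(ci)]] + win, bp)
      nb <- idx[lo:hi]
      R <- crossprod(S[, ci, drop = FALSE], S[, nb, drop = FALSE]) / (n - 1)
      r2 <- R^2
      r2 <- r2 - (1 - r2) / (n - 2)
      inwin <- abs(outer(meta$bp[ci], meta$bp[nb], "-")) <= win
      l2[ci] <- rowSums(r2 * inwin)
    }
  }
  structure(data.frame(SNP = meta$snp, L2 = l2, stringsAsFactors = FALSE),
            M = m, n = n, class = c("ld_scores", "data.frame"))
}

# Contiguous near-equal block assignment (sizes differ by at most 1).
block_assign <- function(m, n_blocks) {
  if (m < n_blocks) {
    warn_ipw("fewer SNPs (%d) than blocks (%d); reducing block count", m, n_blocks)
    n_blocks <- m
  }
  sizes <- rep(m %/% n_blocks, n_blocks)
  extra <- m %% n_blocks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_blocks), times = sizes)
}

# Weighted regression with intercept via sufficient statistics, plus exact
# delete-one-block estimates. Returns slope/intercept totals and per-block
# leave-one-out series.
jackknife_wls <- function(x, y, v, blocks) {
  sums <- function(idx) c(sv = sum(v[idx]), sx = sum(v[idx] * x[idx]),
                          sy = sum(v[idx] * y[idx]),
                          sxx = sum(v[idx] * x[idx]^2),
                          sxy = sum(v[idx] * x[idx] * y[idx]))
  per <- t(vapply(split(seq_along(x), blocks), sums, numeric(5)))
  tot <- colSums(per)
  est <- function(s) {
    den <- s[["sv"]] * s[["sxx"]] - s[["sx"]]^2
    slope <- (s[["sv"]] * s[["sxy"]] - s[["sx"]] * s[["sy"]]) / den
    c(slope = slope,
      intercept = (s[["sy"]] - slope * s[["sx"]]) / s[["sv"]])
  }
  full <- est(tot)
  loo <- t(apply(per, 1, function(b) est(tot - b)))
  B <- nrow(loo)
  jse <- function(th) sqrt((B - 1) / B * sum((th - mean(th))^2))
  list(slope = full[["slope"]], intercept = full[["intercept"]],
       slope_se = jse(loo[, "slope"]), intercept_se = jse(loo[, "intercept"]),
       loo_slope = loo[, "slope"], loo_intercept = loo[, "intercept"],
       n_blocks = B)
}

#' LD-score regression heritability
#'
#' Weighted regression of the per-SNP association chi-square `Z^2` on
#' `n * l_j / M` with a free intercept: the slope estimates the
#' observed-scale SNP heritability and the intercept captures confounding
#' inflation (1 in its absence). Standard errors come from a delete-one
#' block jackknife over contiguous near-equal SNP blocks (default 200).
#' Regression weights are `1 / max(l_j, 1)`.
#'
#' @param ss Summary statistics with `SNP`, `Z` and `N` (effective sample
#'   size in the weighted arm).
#' @param ld An [compute_ld_scores()] result (or data frame `SNP`, `L2`).
#' @param n Sample size; defaults to the median of `ss$N`.
#' @param n_blocks Jackknife blocks (default 200).
#' @param K,P_sample Optional population prevalence and sample case fraction
#'   of a binary trait: when both are given the estimate is also reported on
#'   the liability scale.
#' @return An `ldsc_fit` list: `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `loo_h2` (delete-one-block series), `M`, `n`, and `h2_liab`/`h2_liab_se`
#'   when a prevalence is supplied.
#' @export
estimate_h2 <- function(ss, ld, n = NULL, n_blocks = 200L,
                        K = NULL, P_sample = NULL) {
  dat <- merge(ss[, c("SNP", "Z", "N")], ld, by = "SNP", sort = FALSE)
  dat <- dat[match(intersect(ld$SNP, ss$SNP), dat$SNP), ]
  if (!nrow(dat)) stop_ipw("no shared SNPs between summary stats and LD scores")
  M <- attr(ld, "M") %||% nrow(ld)
  n <- n %||% stats::median(dat$N, na.rm = TRUE)
  x <- n * dat$L2 / M
  y <- dat$Z^2
  v <- 1 / pmax(dat$L2, 1)
  blocks <- block_assign(nrow(dat), n_blocks)
  jk <- jackknife_wls(x, y, v, blocks)
  out <- list(h2 = jk$slope, h2_se = jk$slope_se,
              intercept = jk$intercept, intercept_se = jk$intercept_se,
              loo_h2 = jk$loo_slope, loo_intercept = jk$loo_intercept,
              n_blocks = jk$n_blocks, M = M, n = n)
  if (!is.null(K) && !is.null(P_sample)) {
    mult <- liability_multiplier(K, P_sample)
    out$h2_liab <- out$h2 * mult
    out$h2_liab_se <- out$h2_se * mult
    out$loo_h2_liab <- out$loo_h2 * mult
  }
  structure(out, class = "ldsc_fit")
}

#' LD-score regression genetic correlation
#'
#' Cross-trait regression of `Z1 * Z2` on `sqrt(n1 * n2) * l_j / M`
#' estimates the genetic covariance; dividing by the square root of the two
#' heritabilities gives the genetic correlation. All three regressions share
#' the same jackknife blocks, so a delete-one-block series of r_g is exact.
#' Effect alleles are harmonized between the two traits (Z flipped when the
#' allele pair is swapped; mismatching pairs are an error).
#'
#' @param ss1,ss2 Summary statistics of the two traits (shared SNP subset is
#'   used), with columns `SNP`, `A1`, `A2`, `Z`, `N`.
#' @param ld LD scores.
#' @param n1,n2 Sample sizes (defaults: median of each `N`).
#' @param n_blocks Jackknife blocks.
#' @return An `rg_fit` list: `rg`, `rg_se`, `gencov`, `h2_1`, `h2_2`,
#'   `loo_rg`, `n_blocks`; `rg` is `NA` (flagged) if either heritability is
#'   non-positive, and flagged `out_of_range` if outside `[-1, 1]`.
#' @export
estimate_rg <- function(ss1, ss2, ld, n1 = NULL, n2 = NULL, n_blocks = 200L) {
  shared <- intersect(intersect(ss1$SNP, ss2$SNP), ld$SNP)
  if (!length(shared)) stop_ipw("no shared SNPs")
  i1 <- match(shared, ss1$SNP); i2 <- match(shared, ss2$SNP)
  il <- match(shared, ld$SNP)
  z1 <- ss1$Z[i1]; z2 <- ss2$Z[i2]
  if (all(c("A1", "A2") %in% names(ss1)) && all(c("A1", "A2") %in% names(ss2))) {
    same <- ss1$A1[i1] == ss2$A1[i2] & ss1$A2[i1] == ss2$A2[i2]
    flip <- ss1$A1[i1] == ss2$A2[i2] & ss1$A2[i1] == ss2$A1[i2]
    if (any(!same & !flip)) stop_ipw("allele coding mismatch between traits")
    z2[flip] <- -z2[flip]
  }
  ord <- order(il)
  z1 <- z1[ord]; z2 <- z2[ord]
  l2 <- ld$L2[il][ord]
  M <- attr(ld, "M") %||% nrow(ld)
  n1 <- n1 %||% stats::median(ss1$N[i1], na.rm = TRUE)
  n2 <- n2 %||% stats::median(ss2$N[i2], na.rm = TRUE)
  v <- 1 / pmax(l2, 1)
  blocks <- block_assign(length(z1), n_blocks)
  jk1 <- jackknife_wls(n1 * l2 / M, z1^2, v, blocks)
  jk2 <- jackknife_wls(n2 * l2 / M, z2^2, v, blocks)
  jkc <- jackknife_wls(sqrt(n1 * n2) * l2 / M, z1 * z2, v, blocks)
  rg_of <- function(cov, h1, h2) {
    out <- rep(NA_real_, length(cov))
    ok <- h1 > 0 & h2 > 0
    out[ok] <- cov[ok] / sqrt(h1[ok] * h2[ok])
    out
  }
  rg <- rg_of(jkc$slope, jk1$slope, jk2$slope)
  loo_rg <- rg_of(jkc$loo_slope, jk1$loo_slope, jk2$loo_slope)
  B <- jkc$n_blocks
  rg_se <- if (anyNA(loo_rg)) NA_real_ else
    sqrt((B - 1) / B * sum((loo_rg - mean(loo_rg))^2))
  structure(list(rg = rg, rg_se = rg_se, gencov = jkc$slope,
                 h2_1 = jk1$slope, h2_2 = jk2$slope,
                 loo_rg = loo_rg, n_blocks = B,
                 flagged = is.na(rg),
                 out_of_range = !is.na(rg) && abs(rg) > 1),
            class = "rg_fit")
}

# Observed-to-liability scale multiplier.
liability_multiplier <- function(K, P_sample) {
  assert_prob(K, "K"); assert_prob(P_sample, "P_sample")
  z <- dnorm(qnorm(K))
  K^2 * (1 - K)^2 / (P_sample * (1 - P_sample) * z^2)
}

#' Convert observed-scale heritability to the liability scale
#'
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (P (1-P) z^2)` where `K` is the
#' population prevalence, `P` the sample case fraction and `z` the standard
#' normal density at the prevalence threshold. In the weighted arm the
#' population prevalence is taken as the weighted sample prevalence; the
#' unweighted arm uses the raw sample prevalence.
#'
#' @param h2_obs Observed-scale heritability.
#' @param K Population prevalence in (0, 1).
#' @param P_sample Sample case fraction in (0, 1).
#' @return Liability-scale heritability.
#' @examples
#' liability_conversion(1, 0.5, 0.5)  # pi / 2
#' @export
liability_conversion <- function(h2_obs, K, P_sample) {
  h2_obs * liability_multiplier(K, P_sample)
}

#' Correlation between two paired jackknife series
#'
#' Pearson correlation of the raw delete-one-block estimates of two
#' quantities computed from overlapping data; feeds the difference test's
#' covariance term. (With equal block sizes the correlation is invariant to
#' the affine pseudovalue transform, so raw delete-one estimates are used.)
#'
#' @param est_blocks_a,est_blocks_b Equal-length delete-one-block series.
#' @return Correlation in `[-1, 1]`; 0 with a warning when either series is
#'   constant.
#' @export
jackknife_correlation <- function(est_blocks_a, est_blocks_b) {
  if (length(est_blocks_a) != length(est_blocks_b))
    stop_ipw("jackknife series must have equal length")
  if (sd(est_blocks_a) == 0 || sd(est_blocks_b) == 0) {
    warn_ipw("zero variance in a jackknife series; correlation undefined, using 0")
    return(0)
  }
  cor(est_blocks_a, est_blocks_b)
}

#' Difference test between paired weighted and unweighted estimates
#'
#' Tests `diff = est_a - est_b` with
#' `se_diff = sqrt(se_a^2 + se_b^2 - 2 r se_a se_b)` where `r` is the
#' jackknife correlation between the paired estimates (they share data, so
#' independence would overstate the variance); `Z = diff / se_diff` with a
#' two-sided normal P-value. Vectorized over estimate pairs;
#' Benjamini-Hochberg adjusted P-values are appended across the batch.
#'
#' @param est_a,est_b Paired estimates.
#' @param se_a,se_b Their standard errors.
#' @param r Jackknife correlation(s) between the pairs, in `[-1, 1]`.
#' @return Data frame with `diff`, `se_diff`, `Z`, `P`, `P_FDR`.
#' @examples
#' difference_test(0.3, 0.1, 0.05, 0.05, 0.5)  # Z = 4
#' @export
difference_test <- function(est_a, est_b, se_a, se_b, r) {
  if (any(!is.finite(c(est_a, est_b, se_a, se_b, r))))
    stop_ipw("difference test inputs must be finite")
  if (any(abs(r) > 1)) stop_ipw("r must lie in [-1, 1]")
  v <- se_a^2 + se_b^2 - 2 * r * se_a * se_b
  diff <- est_a - est_b
  # r = 1 with equal SEs gives a zero variance; only legitimate for a zero
  # difference (identical arms), anything else is inconsistent input
  degenerate <- v <= 1e-300 & abs(diff) < 1e-12
  if (any(v <= 0 & !degenerate))
    stop_ipw("non-positive difference variance: inconsistent inputs")
  se_diff <- sqrt(pmax(v, 0))
  Z <- ifelse(degenerate, 0, diff / se_diff)
  P <- 2 * pnorm(-abs(Z))
  data.frame(diff = diff, se_diff = se_diff, Z = Z, P = P,
             P_FDR = fdr_adjust(P))
}
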