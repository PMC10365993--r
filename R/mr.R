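#' Select genetic instruments from both scan arms
#'
#' Pools SNPs reaching the significance threshold in either the standard or
#' the weighted exposure scan, clumps them greedily to an approximately
#' LD-independent set using the minimum P across arms (default window
#' 10,000 kb and r^2 0.001, the conventional Mendelian-randomization
#' pruning), and flags each retained instrument with its arm of discovery
#' (`GWA`, `wGWA` or `both`). Exposures yielding fewer than
#' `min_instruments` (default 10) instruments are excluded.
#'
#' @param ss_exp,ss_exp_w Exposure summary statistics of the standard and
#'   weighted arms on a shared SNP universe.
#' @param g `genotype_set` for the LD computation.
#' @param threshold Significance threshold (default 5e-8).
#' @param window_kb,r2_max Clumping parameters.
#' @param min_instruments Minimum instrument count.
#' @return An `instrument_set` list: `snps`, per-SNP `arm` flags, `m`, and
#'   `excluded`/`reason` when the exposure fails the instrument-count rule.
#' @export
select_instruments <- function(ss_exp, ss_exp_w, g, threshold = 5e-8,
                               window_kb = 10000, r2_max = 0.001,
                               min_instruments = 10L) {
  if (!identical(sort(ss_exp$SNP), sort(ss_exp_w$SNP)))
    stop_ipw("the two arms cover different SNP universes")
  i2 <- match(ss_exp$SNP, ss_exp_w$SNP)
  sig <- !is.na(ss_exp$P) & ss_exp$P < threshold
  sig_w <- !is.na(ss_exp_w$P[i2]) & ss_exp_w$P[i2] < threshold
  pooled <- ss_exp
  pooled$P <- pmin(ss_exp$P, ss_exp_w$P[i2], na.rm = TRUE)
  pooled <- pooled[sig | sig_w, , drop = FALSE]
  excl <- function(reason) structure(
    list(snps = character(0), arm = character(0), m = 0L,
         excluded = TRUE, reason = reason), class = "instrument_set")
  if (!nrow(pooled)) return(excl("no genome-wide significant SNP in either arm"))
  leads <- clump(pooled, g, window_kb = window_kb, r2_max = r2_max,
                 p_threshold = 1)  # pooled rows are already significant
  if (length(leads) < min_instruments)
    return(excl(sprintf("only %d instrument(s) after clumping (minimum %d)",
                        length(leads), min_instruments)))
  il <- match(leads, ss_exp$SNP)
  arm <- ifelse(sig[il] & sig_w[match(leads, ss_exp$SNP)], "both",
                ifelse(sig[il], "GWA", "wGWA"))
  structure(list(snps = leads, arm = arm, m = length(leads),
                 excluded = FALSE, reason = NULL),
            class = "instrument_set")
}

#' Extract harmonized instrument effects for one arm
#'
#' Pulls the standardized SNP effects and standard errors of the selected
#' instruments from an exposure and an outcome summary-statistics table,
#' harmonizing effect alleles (outcome effects are flipped when the allele
#' pair is swapped; a mismatching pair is an error).
#'
#' @param instruments An `instrument_set` (or character vector of SNP ids).
#' @param ss_exp,ss_out Exposure and outcome summary statistics containing
#'   `SNP`, `A1`, `A2`, `BETA_STD`, `SE_STD`.
#' @return Data frame with `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @export
instrument_effects <- function(instruments, ss_exp, ss_out) {
  snps <- if (inherits(instruments, "instrument_set")) instruments$snps else instruments
  ie <- match(snps, ss_exp$SNP); io <- match(snps, ss_out$SNP)
  if (anyNA(ie) || anyNA(io)) stop_ipw("instrument SNPs missing from summary stats")
  flip <- rep(1, length(snps))
  if (all(c("A1", "A2") %in% names(ss_exp)) && all(c("A1", "A2") %in% names(ss_out))) {
    same <- ss_exp$A1[ie] == ss_out$A1[io] & ss_exp$A2[ie] == ss_out$A2[io]
    sw <- ss_exp$A1[ie] == ss_out$A2[io] & ss_exp$A2[ie] == ss_out$A1[io]
    if (any(!same & !sw)) stop_ipw("allele coding mismatch between exposure and outcome")
    flip[sw] <- -1
  }
  data.frame(snp = snps,
             beta_exp = ss_exp$BETA_STD[ie], se_exp = ss_exp$SE_STD[ie],
             beta_out = flip * ss_out$BETA_STD[io], se_out = ss_out$SE_STD[io],
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted Mendelian randomization
#'
#' Combines the per-SNP ratio estimates `alpha_j = beta_out_j / beta_exp_j`
#' with weights `u_j = (beta_exp_j / se_out_j)^2`:
#' `alpha_IVW = sum(u_j alpha_j) / sum(u_j)` and `Var = 1 / sum(u_j)`,
#' identical to a weighted through-origin regression of outcome effects on
#' exposure effects with weights `1 / se_out^2`.
#'
#' @param instruments Data frame from [instrument_effects()] (columns
#'   `beta_exp`, `beta_out`, `se_out`, and `se_exp` for the correction).
#' @return An `mr_fit` list: `alpha`, `se`, `var`, per-SNP `ratio` estimates
#'   and the instrument table. SNPs with a zero exposure effect are dropped
#'   with a warning.
#' @export
ivw <- function(instruments) {
  ins <- instruments
  zero <- ins$beta_exp == 0
  if (any(zero)) {
    warn_ipw("dropping %d instrument(s) with zero exposure effect", sum(zero))
    ins <- ins[!zero, , drop = FALSE]
  }
  if (nrow(ins) < 1L) stop_ipw("no usable instruments")
  u <- (ins$beta_exp / ins$se_out)^2
  ratio <- ins$beta_out / ins$beta_exp
  alpha <- sum(u * ratio) / sum(u)
  v <- 1 / sum(u)
  structure(list(alpha = alpha, se = sqrt(v), var = v,
                 ratio = ratio, m = nrow(ins), instruments = ins),
            class = "mr_fit")
}

#' Selection correction of the IVW estimate
#'
#' Instruments chosen for genome-wide significance carry noisy exposure
#' effects, attenuating the IVW estimate. The correction rescales by the
#' ratio of the observed exposure-effect variance
#' `S^2 = Var(beta_exp)` to its noise-free part
#' `sigma2 = S^2 - mean(Var(beta_exp_j))`:
#' `alpha_corrected = alpha_IVW * S^2 / sigma2` and
#' `Var(alpha_corrected) = Var(alpha_IVW) * S^2 / sigma2`. When
#' `sigma2 <= 0` the correction is undefined; the uncorrected fit is
#' returned flagged, with a warning.
#'
#' @param fit An [ivw()] fit.
#' @param instruments Instrument table with `beta_exp` and `se_exp`
#'   (defaults to the fit's own table).
#' @param mode `"variance"` (default) applies the dimensionless factor
#'   `S^2 / sigma2` to the estimate; `"as_printed"` divides the estimate by
#'   `sigma` (the square root) instead, for audit of the alternative
#'   reading.
#' @return The fit extended with `S2`, `sigma2`, `correction_factor`,
#'   `alpha_corrected`, `se_corrected`, `var_corrected` and
#'   `correction_flagged`.
#' @export
corrected_ivw <- function(fit, instruments = NULL,
                          mode = c("variance", "as_printed")) {
  mode <- match.arg(mode)
  ins <- instruments %||% fit$instruments
  m <- nrow(ins)
  if (m < 2L) stop_ipw("the selection correction needs at least 2 instruments")
  S2 <- var(ins$beta_exp)
  sigma2 <- S2 - mean(ins$se_exp^2)
  out <- fit
  out$S2 <- S2; out$sigma2 <- sigma2
  if (sigma2 <= 0) {
    warn_ipw("non-positive noise-free exposure variance; correction undefined")
    out$correction_flagged <- TRUE
    out$correction_factor <- NA_real_
    out$alpha_corrected <- fit$alpha
    out$var_corrected <- fit$var
    out$se_corrected <- fit$se
    return(out)
  }
  fac <- S2 / sigma2
  out$correction_flagged <- FALSE
  out$correction_factor <- fac
  out$alpha_corrected <- if (mode == "variance") fit$alpha * fac
                         else fit$alpha * S2 / sqrt(sigma2)
  out$var_corrected <- fit$var * fac
  out$se_corrected <- sqrt(out$var_corrected)
  out
}

#' Difference between standard and weighted MR estimates
#'
#' Computes `alpha_DIFF = alpha - alpha_w` with
#' `se = sqrt(se^2 + se_w^2 - 2 r se se_w)`, where `r` is the correlation of
#' the two estimates across a leave-one-SNP-out jackknife (MR is re-run
#' leaving out each instrument in turn in both arms, and `r` is the
#' correlation of the resulting estimate pairs).
#'
#' @param instruments_std,instruments_w Instrument tables of the two arms
#'   ([instrument_effects()]) over the same SNPs, in the same order.
#' @return List with `fit_std`, `fit_w`, `r`, and a one-row `test` data
#'   frame (`diff`, `se_diff`, `Z`, `P`, `P_FDR`).
#' @export
mr_difference <- function(instruments_std, instruments_w) {
  if (!identical(instruments_std$snp, instruments_w$snp))
    stop_ipw("arms must share the same instruments in the same order")
  m <- nrow(instruments_std)
  if (m < 3L) stop_ipw("leave-one-out jackknife needs at least 3 instruments")
  fit_std <- ivw(instruments_std)
  fit_w <- ivw(instruments_w)
  loo <- vapply(seq_len(m), function(j) {
    c(ivw(instruments_std[-j, , drop = FALSE])$alpha,
      ivw(instruments_w[-j, , drop = FALSE])$alpha)
  }, numeric(2))
  r <- jackknife_correlation(loo[1, ], loo[2, ])
  test <- difference_test(fit_std$alpha, fit_w$alpha, fit_std$se, fit_w$se, r)
  list(fit_std = fit_std, fit_w = fit_w, r = r, loo = t(loo), test = test)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted P-values controlling the FDR, applied across all tests
#' of one pipeline invocation (thin wrapper over [stats::p.adjust()]).
#'
#' @param p_values Raw P-values in `[0, 1]`.
#' @return Adjusted P-values, monotone non-decreasing in raw rank.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_ipw("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
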