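#' Genome-wide scan configuration
#'
#' @param sig_threshold Genome-wide significance threshold (default 5e-8;
#'   configurable for desk-scale runs).
#' @param robust_unweighted Report Huber-White (sandwich) standard errors in
#'   the unweighted arm as well; by default the unweighted arm reports
#'   classical homoskedastic ordinary-least-squares standard errors.
#' @return A `gwas_config` list.
#' @export
gwas_config <- function(sig_threshold = 5e-8, robust_unweighted = FALSE) {
  if (sig_threshold <= 0 || sig_threshold >= 1)
    stop_ipw("sig_threshold must lie in (0, 1)")
  structure(list(sig_threshold = sig_threshold,
                 robust_unweighted = robust_unweighted),
            class = "gwas_config")
}

#' Quality-control filter for a genotype panel
#'
#' Retains SNPs with minor-allele frequency above `maf_min`, call rate above
#' `call_rate_min`, and a Hardy-Weinberg chi-square test P above
#' `hwe_p_min`.
#'
#' @param g A `genotype_set` (dosages may contain `NA`).
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param call_rate_min Minimum per-SNP call rate (default 0.90).
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium P (default 1e-6).
#' @return Filtered `genotype_set`; attribute `qc_report` counts removals per
#'   criterion. A warning (not an error) is raised if no SNP survives.
#' @export
qc_filter <- function(g, maf_min = 0.01, call_rate_min = 0.90,
                      hwe_p_min = 1e-6) {
  d <- g$dosages
  n_tot <- nrow(d)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  nn <- n0 + n1 + n2
  call_rate <- nn / n_tot
  p <- (n1 + 2 * n2) / (2 * pmax(nn, 1L))
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_chisq_p(n0, n1, n2)
  keep_maf <- maf > maf_min
  keep_cr <- call_rate > call_rate_min
  keep_hwe <- hwe_p > hwe_p_min
  keep <- keep_maf & keep_cr & keep_hwe
  if (!any(keep)) warn_ipw("no SNP passed quality control")
  out <- g
  out$dosages <- d[, keep, drop = FALSE]
  out$snp_meta <- g$snp_meta[keep, , drop = FALSE]
  rownames(out$snp_meta) <- NULL
  if (!is.null(g$block)) out$block <- g$block[keep]
  attr(out, "qc_report") <- data.frame(
    criterion = c("maf", "call_rate", "hwe"),
    removed = c(sum(!keep_maf), sum(!keep_cr), sum(!keep_hwe)))
  out
}

# Chi-square (1 df) Hardy-Weinberg test from genotype counts.
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * pmax(n, 1L))
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  stat <- rep(Inf, length(n))
  ok <- e0 > 0 & e1 > 0 & e2 > 0
  stat[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  # monomorphic SNPs carry no HWE information
  mono <- p == 0 | p == 1
  stat[mono] <- 0
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Leading principal components of a genotype panel
#'
#' Truncated SVD of the column-standardized dosage matrix; the standard
#' population-structure covariates of a genome-wide scan.
#'
#' @param g A `genotype_set` (QC-filtered).
#' @param k Number of components (default 5).
#' @return n x k matrix of PC scores, columns `PC1..PCk`.
#' @export
genotype_pcs <- function(g, k = 5L) {
  S <- scale(g$dosages)
  S[is.na(S) | is.nan(S)] <- 0
  n <- nrow(S); m <- ncol(S)
  k <- min(k, m - 1L, n - 1L)
  # eigen-decompose on the smaller dimension: scores = U d
  if (n <= m) {
    e <- eigen(tcrossprod(S), symmetric = TRUE)
    pcs <- e$vectors[, seq_len(k), drop = FALSE] *
      rep(sqrt(pmax(e$values[seq_len(k)], 0)), each = n)
  } else {
    e <- eigen(crossprod(S), symmetric = TRUE)
    pcs <- S %*% e$vectors[, seq_len(k), drop = FALSE]
  }
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Per-SNP (weighted) least-squares association scan
#'
#' For each SNP, regresses the phenotype on the SNP dosage, the covariates
#' and an intercept. With weights the estimator is weighted least squares,
#' `beta_w = (X'WX)^{-1} X'WY`, and its variance is the Huber-White sandwich
#' `(X'WX)^{-1} (X'WDWX) (X'WX)^{-1}` with `D = diag[(Y - X beta_w)^2]`,
#' since sampling weights violate homoskedasticity. Without weights the
#' classical homoskedastic ordinary-least-squares variance is reported
#' (sandwich optionally, see [gwas_config()]). Binary phenotypes are coded
#' 0/1 and analysed with the same linear model. Two-sided P-values use the
#' normal approximation.
#'
#' Standardized effects `beta_std = Z / sqrt(2p(1-p)(n + Z^2))` are appended,
#' using the weighted allele frequency and the effective sample size in the
#' weighted arm.
#'
#' @param g A `genotype_set`.
#' @param y Phenotype vector aligned to the rows of `g$dosages`.
#' @param config A [gwas_config()].
#' @param weights Optional positive weights (or `probability_weights`),
#'   aligned to rows.
#' @param covariates Optional numeric covariate matrix aligned to rows
#'   (e.g. `cbind(genotype_pcs(g), sex, age)`).
#' @return A summary-statistics data frame with columns `SNP`, `CHR`, `BP`,
#'   `A1`, `A2`, `FREQ`, `BETA`, `SE`, `Z`, `P`, `N`, `BETA_STD`, `SE_STD`.
#'   `N` is the analysis sample size, or the effective sample size in the
#'   weighted arm. SNPs with rank-deficient designs are skipped (`NA` rows,
#'   reason in attribute `skipped`).
#' @export
run_scan <- function(g, y, config = gwas_config(), weights = NULL,
                     covariates = NULL) {
  d <- g$dosages
  n_all <- nrow(d)
  if (length(y) != n_all) stop_ipw("phenotype length must match genotype rows")
  if (inherits(weights, "probability_weights")) weights <- weights$w
  weighted <- !is.null(weights)
  if (weighted && (length(weights) != n_all || any(weights <= 0)))
    stop_ipw("weights must be positive and aligned to genotype rows")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_all) stop_ipw("covariates not aligned to genotypes")
  }
  keep <- !is.na(y)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  d <- d[keep, , drop = FALSE]; y <- y[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  w <- if (weighted) weights[keep] else rep(1, sum(keep))
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  kc <- ncol(C)
  use_sandwich <- weighted || config$robust_unweighted
  m <- ncol(d)
  beta <- se <- freq <- nobs <- rep(NA_real_, m)
  skipped <- character(0)
  wC <- C * w
  CWC <- crossprod(C, wC)
  CWy <- crossprod(wC, y)
  has_na <- anyNA(d)
  n_eff <- effective_sample_size(w)
  for (j in seq_len(m)) {
    gj <- as.numeric(d[, j])
    if (has_na && anyNA(gj)) {
      ok <- !is.na(gj)
      Xj <- cbind(gj[ok], C[ok, , drop = FALSE])
      wj <- w[ok]; yj <- y[ok]
      XWX <- crossprod(Xj, Xj * wj)
      XWy <- crossprod(Xj * wj, yj)
      nj <- sum(ok)
      n_eff_j <- effective_sample_size(wj)
      fq <- sum(wj * gj[ok]) / (2 * sum(wj))
    } else {
      gw <- gj * w
      XWX <- rbind(c(sum(gw * gj), crossprod(gw, C)),
                   cbind(crossprod(C, gw), CWC))
      XWy <- c(crossprod(gw, y), CWy)
      Xj <- NULL
      nj <- n
      n_eff_j <- n_eff
      fq <- sum(gw) / (2 * sum(w))
    }
    b <- tryCatch(solve(XWX, XWy), error = function(e) NULL)
    if (is.null(b)) { skipped <- c(skipped, g$snp_meta$snp[j]); next }
    if (is.null(Xj)) {
      fit_res <- y - gj * b[1] - C %*% b[-1]
      wj <- w; Xfull <- cbind(gj, C)
    } else {
      fit_res <- yj - Xj %*% b
      Xfull <- Xj
    }
    XWXi <- solve(XWX)
    if (use_sandwich) {
      u <- as.numeric(fit_res) * wj
      meat <- crossprod(Xfull * u)
      V <- XWXi %*% meat %*% XWXi
      se[j] <- sqrt(V[1, 1])
    } else {
      s2 <- sum(fit_res^2) / (nj - (kc + 1L))
      se[j] <- sqrt(s2 * XWXi[1, 1])
    }
    beta[j] <- b[1]
    freq[j] <- fq
    nobs[j] <- if (weighted) n_eff_j else nj
  }
  z <- beta / se
  std <- standardize_effects(z, freq, nobs)
  out <- data.frame(
    SNP = g$snp_meta$snp, CHR = g$snp_meta$chr, BP = g$snp_meta$bp,
    A1 = g$snp_meta$a1, A2 = g$snp_meta$a2,
    FREQ = freq, BETA = beta, SE = se, Z = z,
    P = 2 * pnorm(-abs(z)), N = nobs,
    BETA_STD = std$beta_std, SE_STD = std$se_std,
    stringsAsFactors = FALSE
  )
  attr(out, "weighted") <- weighted
  attr(out, "skipped") <- skipped
  out
}

#' Standardize SNP effects from summary statistics
#'
#' `beta_std = Z / sqrt(2p(1-p)(n + Z^2))` and
#' `se_std = 1 / sqrt(2p(1-p)(n + Z^2))`: the effect of the genotype on the
#' standardized outcome, recoverable from the Z-score, allele frequency and
#' sample size alone. In weighted analyses `n` is the effective sample size
#' and `p` the weighted allele frequency.
#'
#' @param z Z statistics.
#' @param p Allele frequencies strictly inside (0, 1).
#' @param n Sample sizes (or effective sample sizes), positive.
#' @return List with `beta_std` and `se_std`; `beta_std / se_std` equals `z`.
#' @export
standardize_effects <- function(z, p, n) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] >= 1)) stop_ipw("allele frequencies must be in (0, 1)")
  if (any(n[ok & !is.na(n)] <= 0)) stop_ipw("n must be positive")
  denom <- sqrt(2 * p * (1 - p) * (n + z^2))
  list(beta_std = z / denom, se_std = 1 / denom)
}

#' Compare a standard and a weighted scan
#'
#' For every SNP reaching the significance threshold in either arm, assigns
#' a discovery class (`GWA-only`, `wGWA-only`, `both`), the relative effect
#' change `(|beta| - |beta_w|) / |beta|`, a change class (`reduced` if the
#' relative change is >= `change_threshold`, `increased` if <= minus it,
#' else `stable`) and a sign-flip flag.
#'
#' @param ss,ss_w Summary statistics of the standard and weighted arms on the
#'   same SNP universe.
#' @param threshold Significance threshold.
#' @param change_threshold Relative-change boundary (default 0.2).
#' @return List with the per-SNP `table` and a `summary` of counts.
#' @export
compare_scans <- function(ss, ss_w, threshold = 5e-8, change_threshold = 0.2) {
  if (!identical(ss$SNP, ss_w$SNP)) stop_ipw("scans cover different SNP sets")
  sig <- ss$P < threshold
  sig_w <- ss_w$P < threshold
  sel <- which((sig | sig_w) & !is.na(sig) & !is.na(sig_w))
  cls <- ifelse(sig[sel] & sig_w[sel], "both",
                ifelse(sig[sel], "GWA-only", "wGWA-only"))
  rel <- (abs(ss$BETA[sel]) - abs(ss_w$BETA[sel])) / abs(ss$BETA[sel])
  chg <- ifelse(rel >= change_threshold, "reduced",
                ifelse(rel <= -change_threshold, "increased", "stable"))
  tab <- data.frame(SNP = ss$SNP[sel], discovery = cls,
                    beta = ss$BETA[sel], beta_w = ss_w$BETA[sel],
                    relative_change = rel, change = chg,
                    sign_flip = sign(ss$BETA[sel]) != sign(ss_w$BETA[sel]),
                    stringsAsFactors = FALSE)
  summary <- list(
    n_significant = length(sel),
    discovery = table(factor(cls, levels = c("GWA-only", "wGWA-only", "both"))),
    change = table(factor(chg, levels = c("reduced", "stable", "increased"))),
    n_sign_flips = sum(tab$sign_flip)
  )
  list(table = tab, summary = summary)
}

#' Genome-wide scan on the participation liability
#'
#' Uses the individual participation probabilities themselves as a
#' continuous outcome in a weighted scan; a standard (unweighted) scan is
#' not meaningful here because the analysis sample is already conditioned on
#' participating.
#'
#' @param g Genotypes of the selected sample.
#' @param P Participation probabilities for the scanned individuals.
#' @param weights Probability weights (required).
#' @param covariates Optional covariates.
#' @param config A [gwas_config()].
#' @return Summary statistics (attribute `liability_proxy = TRUE`).
#' @export
participation_liability_scan <- function(g, P, weights, covariates = NULL,
                                         config = gwas_config()) {
  if (sd(P) == 0) stop_ipw("participation probabilities are constant")
  out <- run_scan(g, P, config = config, weights = weights,
                  covariates = covariates)
  attr(out, "liability_proxy") <- TRUE
  out
}

#' Paired weighted and unweighted scans on biological sex
#'
#' Autosomal SNP effects on sex (coded 0/1) should be null in a
#' representative sample; sex-differential participation induces apparent
#' autosomal effects which weighting should attenuate.
#'
#' @param g Autosomal genotypes.
#' @param sex Sex coded 0/1.
#' @param weights Probability weights for the weighted arm.
#' @param covariates Optional covariates.
#' @param config A [gwas_config()].
#' @param snp_list Optional SNP ids for a per-SNP comparison table.
#' @return List with `unweighted`, `weighted` summary statistics and, when
#'   `snp_list` is given, a `comparison` table of paired effects.
#' @export
sex_scan <- function(g, sex, weights, covariates = NULL,
                     config = gwas_config(), snp_list = NULL) {
  sex <- as.numeric(sex)
  if (!all(sex %in% c(0, 1))) stop_ipw("sex must be coded 0/1")
  ss <- run_scan(g, sex, config = config, covariates = covariates)
  ss_w <- run_scan(g, sex, config = config, weights = weights,
                   covariates = covariates)
  out <- list(unweighted = ss, weighted = ss_w)
  if (!is.null(snp_list)) {
    i <- match(snp_list, ss$SNP)
    out$comparison <- data.frame(SNP = snp_list,
                                 beta = ss$BETA[i], se = ss$SE[i],
                                 beta_w = ss_w$BETA[i], se_w = ss_w$SE[i])
  }
  out
}

#' Greedy LD clumping of significant SNPs
#'
#' Repeatedly takes the smallest-P unassigned SNP below the threshold as a
#' lead SNP and removes all SNPs within `window_kb` (symmetric, 1-based
#' base-pair positions) whose squared correlation with the lead exceeds
#' `r2_max`.
#'
#' @param ss Summary statistics with `SNP`, `CHR`, `BP`, `P`.
#' @param g `genotype_set` providing dosages for the r^2 computation.
#' @param window_kb Physical window in kilobases (default 250).
#' @param r2_max Maximum r^2 with a lead SNP (default 0.1).
#' @param p_threshold Significance threshold for clump membership.
#' @return Character vector of lead SNP ids, in order of selection.
#' @export
clump <- function(ss, g, window_kb = 250, r2_max = 0.1, p_threshold = 5e-8) {
  meta <- g$snp_meta
  for (ch in unique(meta$chr)) {
    bp <- meta$bp[meta$chr == ch]
    if (is.unsorted(bp, strictly = TRUE))
      stop_ipw("SNP positions must be strictly increasing within a chromosome")
  }
  cand <- ss[!is.na(ss$P) & ss$P < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$P), , drop = FALSE]
  leads <- character(0)
  assigned <- logical(nrow(cand))
  col_of <- match(cand$SNP, colnames(g$dosages))
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    leads <- c(leads, cand$SNP[i])
    assigned[i] <- TRUE
    near <- which(!assigned & cand$CHR == cand$CHR[i] &
                    abs(cand$BP - cand$BP[i]) <= window_kb * 1000)
    if (length(near)) {
      gi <- g$dosages[, col_of[i]]
      r2 <- vapply(near, function(j) {
        suppressWarnings(cor(gi, g$dosages[, col_of[j]],
                             use = "complete.obs"))^2
      }, numeric(1))
      assigned[near[!is.na(r2) & r2 > r2_max]] <- TRUE
    }
  }
  leads
}
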