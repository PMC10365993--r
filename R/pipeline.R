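#' Configuration of a full pipeline run
#'
#' @param scenario A [scenario_config()] describing the synthetic study.
#' @param sig_threshold Significance threshold for discovery counting and
#'   instrument selection. The desk-scale default is 1e-5: genome-wide
#'   5e-8 at biobank sample sizes corresponds to far larger samples than the
#'   synthetic cohorts simulated here.
#' @param clump_kb,clump_r2 Clumping window and r^2 for lead-SNP reporting.
#' @param mr_clump_kb,mr_clump_r2,mr_min_instruments Instrument-selection
#'   parameters of the MR stage.
#' @param n_blocks LD-score regression jackknife blocks.
#' @param ldsc_window_kb LD-score window.
#' @param n_pcs Number of genotype principal components used as covariates.
#' @param folds LASSO cross-validation folds.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            sig_threshold = 1e-5,
                            clump_kb = 250, clump_r2 = 0.1,
                            mr_clump_kb = 10000, mr_clump_r2 = 0.001,
                            mr_min_instruments = 10L,
                            n_blocks = 200L, ldsc_window_kb = 1000,
                            n_pcs = 5L, folds = 5L, seed = 1L) {
  if (!inherits(scenario, "scenario_config"))
    scenario <- do.call(scenario_config, scenario)
  structure(list(scenario = scenario, sig_threshold = sig_threshold,
                 clump_kb = clump_kb, clump_r2 = clump_r2,
                 mr_clump_kb = mr_clump_kb, mr_clump_r2 = mr_clump_r2,
                 mr_min_instruments = as.integer(mr_min_instruments),
                 n_blocks = as.integer(n_blocks),
                 ldsc_window_kb = ldsc_window_kb,
                 n_pcs = as.integer(n_pcs), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full participation-bias correction pipeline
#'
#' Orchestrates simulate -> fit weights -> weighted and standard scans ->
#' scan comparison -> LD-score regression (heritability, genetic
#' correlation, difference tests) -> Mendelian randomization -> report.
#' With an output directory, every stage's artifact is persisted as TSV
#' (genotypes additionally as PLINK1 bed/bim/fam) and the report as JSON;
#' each tabular artifact is accompanied by the configuration hash for
#' provenance.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for stage artifacts.
#' @return A `pipeline_report` list with per-stage summaries: weight
#'   distribution quantiles and effective sample size, discovery counts by
#'   class, heritability and genetic-correlation tables with difference
#'   tests, the MR table, and provenance (`config_hash`, seed).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ipw("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  hash <- config_hash(config)
  persist <- !is.null(output_dir)
  if (persist) dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- stage("simulate", simulate_scenario(config$scenario))
  sel_idx <- which(sim$population$participation == 1L)

  ## --- weights -----------------------------------------------------------
  wres <- stage("fit-weights", {
    X <- build_design(sim$stacked)
    fit <- fit_participation_model(
      X, sim$stacked$participation,
      reference_design_weights = sim$reference$design_weight,
      n_folds = config$folds, seed = config$seed + 101L)
    pw <- compute_weights(fit$P)
    report <- bias_report(sim$reference, sim$selected, pw$w)
    list(fit = fit, pw = pw, report = report)
  })
  pw <- wres$pw

  ## --- scans -------------------------------------------------------------
  gsel <- sim$genotypes
  gsel$dosages <- gsel$dosages[sel_idx, , drop = FALSE]
  gsel <- stage("qc", qc_filter(gsel))
  scan_cfg <- gwas_config(sig_threshold = config$sig_threshold)
  covars <- stage("covariates", {
    pcs <- genotype_pcs(gsel, config$n_pcs)
    cbind(pcs,
          sex = as.numeric(sim$selected$sex == "female"),
          age = sim$selected$age)
  })
  traits <- c("exposure", "outcome")
  scans <- stage("gwas", {
    out <- list()
    for (tr in traits) {
      y <- sim$selected[[tr]]
      out[[tr]] <- list(
        std = run_scan(gsel, y, scan_cfg, covariates = covars),
        wgt = run_scan(gsel, y, scan_cfg, weights = pw$w, covariates = covars))
    }
    out
  })
  comparisons <- stage("compare-gwas", lapply(scans, function(s)
    compare_scans(s$std, s$wgt, threshold = config$sig_threshold)))

  ## --- ldsc --------------------------------------------------------------
  ld <- stage("ld-scores", compute_ld_scores(gsel, config$ldsc_window_kb))
  ldsc_res <- stage("ldsc", {
    h2 <- lapply(scans, function(s) {
      fa <- estimate_h2(s$std, ld, n_blocks = config$n_blocks)
      fw <- estimate_h2(s$wgt, ld, n_blocks = config$n_blocks)
      r <- jackknife_correlation(fa$loo_h2, fw$loo_h2)
      list(std = fa, wgt = fw, r = r,
           test = difference_test(fa$h2, fw$h2, fa$h2_se, fw$h2_se, r))
    })
    rg_std <- estimate_rg(scans$exposure$std, scans$outcome$std, ld,
                          n_blocks = config$n_blocks)
    rg_wgt <- estimate_rg(scans$exposure$wgt, scans$outcome$wgt, ld,
                          n_blocks = config$n_blocks)
    rg_test <- if (!rg_std$flagged && !rg_wgt$flagged) {
      r <- jackknife_correlation(rg_std$loo_rg, rg_wgt$loo_rg)
      difference_test(rg_std$rg, rg_wgt$rg, rg_std$rg_se, rg_wgt$rg_se, r)
    } else NULL
    list(h2 = h2, rg_std = rg_std, rg_wgt = rg_wgt, rg_test = rg_test)
  })

  ## --- participation-specific scans -------------------------------------
  # a flat mechanism carries no liability signal to scan
  liability <- if (sd(sim$selected$true_P) > 0) {
    stage("liability-scan", participation_liability_scan(
      gsel, sim$selected$true_P, weights = pw$w, covariates = covars,
      config = scan_cfg))
  } else NULL
  sexres <- stage("sex-scan", sex_scan(
    gsel, as.numeric(sim$selected$sex == "female"), weights = pw$w,
    config = scan_cfg))

  ## --- mr ----------------------------------------------------------------
  mr_res <- stage("mr", {
    ins <- select_instruments(scans$exposure$std, scans$exposure$wgt, gsel,
                              threshold = config$sig_threshold,
                              window_kb = config$mr_clump_kb,
                              r2_max = config$mr_clump_r2,
                              min_instruments = config$mr_min_instruments)
    if (ins$excluded) {
      list(instruments = ins)
    } else {
      eff_std <- instrument_effects(ins, scans$exposure$std, scans$outcome$std)
      eff_wgt <- instrument_effects(ins, scans$exposure$wgt, scans$outcome$wgt)
      fit_std <- corrected_ivw(ivw(eff_std))
      fit_wgt <- corrected_ivw(ivw(eff_wgt))
      diff <- mr_difference(eff_std, eff_wgt)
      list(instruments = ins, fit_std = fit_std, fit_wgt = fit_wgt,
           difference = diff)
    }
  })

  report <- structure(list(
    provenance = list(config_hash = hash, seed = config$seed,
                      package_version = as.character(utils::packageVersion("ipwgwas"))),
    sample = list(n_population = nrow(sim$population),
                  n_selected = length(sel_idx),
                  n_reference = nrow(sim$reference),
                  participation_rate = length(sel_idx) / nrow(sim$population)),
    weights = list(
      lambda = wres$fit$lambda,
      n_retained_predictors = wres$fit$n_retained_predictors,
      quantiles = quantile(pw$w_in, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)),
      n_effective = pw$n_effective,
      n_effective_ratio = pw$n_effective / pw$n,
      bias_reduction = bias_reduction_summary(wres$report)),
    gwas = lapply(comparisons, `[[`, "summary"),
    ldsc = list(
      h2 = lapply(ldsc_res$h2, function(h) c(
        h2 = h$std$h2, h2_se = h$std$h2_se, h2_w = h$wgt$h2,
        h2_w_se = h$wgt$h2_se, intercept = h$std$intercept, r = h$r,
        diff_Z = h$test$Z, diff_P = h$test$P)),
      rg = c(rg = ldsc_res$rg_std$rg, rg_w = ldsc_res$rg_wgt$rg,
             diff_Z = if (!is.null(ldsc_res$rg_test)) ldsc_res$rg_test$Z else NA,
             diff_P = if (!is.null(ldsc_res$rg_test)) ldsc_res$rg_test$P else NA)),
    mr = if (mr_res$instruments$excluded) {
      list(excluded = TRUE, reason = mr_res$instruments$reason)
    } else list(
      excluded = FALSE, m = mr_res$instruments$m,
      alpha = mr_res$fit_std$alpha, alpha_corrected = mr_res$fit_std$alpha_corrected,
      alpha_w = mr_res$fit_wgt$alpha, alpha_w_corrected = mr_res$fit_wgt$alpha_corrected,
      diff_Z = mr_res$difference$test$Z, diff_P = mr_res$difference$test$P),
    stages = list(simulation = sim, weights = wres, scans = scans,
                  comparisons = comparisons, ld = ld, ldsc = ldsc_res,
                  liability = liability, sex = sexres, mr = mr_res)
  ), class = "pipeline_report")

  if (persist) {
    p <- function(...) file.path(output_dir, ...)
    write_config(config, p("config.yaml"))
    write_cohort_tsv(sim$stacked, p("cohort.tsv"))
    write_plink(sim$genotypes, p("genotypes"))
    write_weights_tsv(sim$selected$id, pw, p("weights.tsv"))
    utils::write.table(wres$report, p("bias_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (tr in traits) {
      write_sumstats(scans[[tr]]$std, p(sprintf("gwas_%s.tsv", tr)))
      write_sumstats(scans[[tr]]$wgt, p(sprintf("wgwas_%s.tsv", tr)))
    }
    utils::write.table(ld, p("ld_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    slim <- report
    slim$stages <- NULL
    jsonlite::write_json(slim, p("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Participation-bias correction pipeline report\n")
  cat(sprintf("  config %s | seed %d\n", x$provenance$config_hash,
              x$provenance$seed))
  cat(sprintf("  population %d, selected %d (%.1f%%), reference %d\n",
              x$sample$n_population, x$sample$n_selected,
              100 * x$sample$participation_rate, x$sample$n_reference))
  cat(sprintf("  weights: n_effective %.1f (%.2f of n), lambda %.4g, %d predictors\n",
              x$weights$n_effective, x$weights$n_effective_ratio,
              x$weights$lambda, x$weights$n_retained_predictors))
  br <- x$weights$bias_reduction
  cat(sprintf("  bias reduction (pairs with r_diff > 0.05): median %.2f over %d pairs\n",
              br[["median"]], br[["n_pairs"]]))
  for (tr in names(x$gwas)) {
    d <- x$gwas[[tr]]$discovery
    cat(sprintf("  %s scan: %d significant (GWA-only %d, wGWA-only %d, both %d)\n",
                tr, x$gwas[[tr]]$n_significant, d[["GWA-only"]],
                d[["wGWA-only"]], d[["both"]]))
  }
  for (tr in names(x$ldsc$h2)) {
    h <- x$ldsc$h2[[tr]]
    cat(sprintf("  h2 %s: %.3f (se %.3f) vs weighted %.3f (se %.3f), diff Z %.2f\n",
                tr, h[["h2"]], h[["h2_se"]], h[["h2_w"]], h[["h2_w_se"]],
                h[["diff_Z"]]))
  }
  if (!isTRUE(x$mr$excluded)) {
    cat(sprintf("  MR: alpha %.3f (corrected %.3f) vs weighted %.3f (corrected %.3f), diff Z %.2f\n",
                x$mr$alpha, x$mr$alpha_corrected, x$mr$alpha_w,
                x$mr$alpha_w_corrected, x$mr$diff_Z))
  } else {
    cat(sprintf("  MR: exposure excluded (%s)\n", x$mr$reason))
  }
  invisible(x)
}
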