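#' Configuration for a synthetic genotype panel
#'
#' @param n_population Number of individuals to simulate.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 numeric: minor-allele frequencies are drawn
#'   uniformly from this interval, which must lie strictly inside (0, 1).
#' @param ld_block_size SNPs per LD block (1 = independent SNPs). Blocks are
#'   physically contiguous.
#' @param ld_rho Within-block haplotype correlation of the Gaussian copula,
#'   in `[0, 1)`. A length-2 range draws one value per block, which gives
#'   LD scores that vary along the panel.
#' @param bp_spacing Base pairs between adjacent SNPs (positions are 1-based
#'   and strictly increasing).
#' @param chromosome Chromosome label for the panel.
#' @param seed Integer seed controlling the whole draw.
#' @return A `population_config` list.
#' @export
population_config <- function(n_population, n_snps,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 1L, ld_rho = 0,
                              bp_spacing = 2500L, chromosome = 1L,
                              seed = 1L) {
  if (n_population < 1 || n_snps < 1)
    stop_ipw("n_population and n_snps must be positive")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop_ipw("maf_range must be an increasing pair inside (0, 1)")
  if (ld_block_size < 1) stop_ipw("ld_block_size must be >= 1")
  if (any(ld_rho < 0) || any(ld_rho >= 1)) stop_ipw("ld_rho must lie in [0, 1)")
  structure(list(n_population = as.integer(n_population),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = as.numeric(ld_rho),
                 bp_spacing = as.integer(bp_spacing),
                 chromosome = as.integer(chromosome),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Simulate a genotype panel in Hardy-Weinberg proportions with block LD
#'
#' Each SNP's dosage is the sum of two independent haplotypes; within an LD
#' block the haplotype indicators share a block-equicorrelated Gaussian
#' latent (correlation `ld_rho`) thresholded at the allele-frequency
#' quantile, so per-SNP genotypes follow Hardy-Weinberg proportions exactly
#' while adjacent SNPs within a block are correlated and SNPs in different
#' blocks are independent.
#'
#' @param config A [population_config()].
#' @return A `genotype_set`: list with `dosages` (n x m integer matrix of
#'   0/1/2, columns named by SNP id) and `snp_meta` (data frame with columns
#'   `snp`, `chr`, `bp`, `a1`, `a2`, `freq`, where `freq` is the realized
#'   A1 frequency, i.e. mean dosage / 2).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_population; m <- config$n_snps
  bs <- config$ld_block_size
  n_blocks <- ceiling(m / bs)
  local_seeded(config$seed, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    rho_blk <- if (length(config$ld_rho) == 2)
      runif(n_blocks, config$ld_rho[1], config$ld_rho[2])
    else rep(config$ld_rho[1], n_blocks)
    dos <- matrix(0L, n, m)
    thr <- qnorm(maf)
    for (hap in 1:2) {
      for (b in seq_len(n_blocks)) {
        idx <- ((b - 1L) * bs + 1L):min(b * bs, m)
        rho <- rho_blk[b]
        z <- matrix(rnorm(n * length(idx)), n, length(idx))
        if (rho > 0 && length(idx) > 1) {
          shared <- rnorm(n)
          z <- sqrt(rho) * shared + sqrt(1 - rho) * z
        }
        dos[, idx] <- dos[, idx] +
          (z < matrix(thr[idx], n, length(idx), byrow = TRUE))
      }
    }
    storage.mode(dos) <- "integer"
    snp <- sprintf("rs%06d", seq_len(m))
    colnames(dos) <- snp
    meta <- data.frame(
      snp = snp, chr = config$chromosome,
      bp = seq_len(m) * config$bp_spacing,
      a1 = "A", a2 = "G",
      freq = unname(colMeans(dos)) / 2,
      stringsAsFactors = FALSE
    )
    structure(list(dosages = dos, snp_meta = meta,
                   block = rep(seq_len(n_blocks), each = bs)[seq_len(m)]),
              class = "genotype_set")
  })
}

#' Additive polygenic trait model
#'
#' @param causal_effects Per-SNP additive effects (length = number of SNPs;
#'   zeros for non-causal SNPs).
#' @param h2_target Target narrow-sense heritability in `[0, 1]`: residual
#'   noise is scaled so the realized genetic variance share equals it.
#' @param prevalence For a binary trait, the case fraction K in (0, 1)
#'   obtained by thresholding the liability; `NULL` for a continuous trait.
#' @return A `trait_model` list.
#' @export
trait_model <- function(causal_effects, h2_target, prevalence = NULL) {
  if (h2_target < 0 || h2_target > 1) stop_ipw("h2_target must lie in [0, 1]")
  if (!is.null(prevalence)) assert_prob(prevalence, "prevalence")
  structure(list(causal_effects = as.numeric(causal_effects),
                 h2_target = h2_target, prevalence = prevalence),
            class = "trait_model")
}

#' Simulate a phenotype from a genotype panel
#'
#' The genetic value is the centred dosage matrix times the causal effects;
#' Gaussian noise is added with variance chosen so that the realized genetic
#' variance share equals `h2_target`. Binary traits threshold the liability
#' at its (1 - K) sample quantile so the case fraction equals the requested
#' prevalence.
#'
#' @param g A `genotype_set`.
#' @param model A [trait_model()].
#' @param seed Integer seed.
#' @return Numeric phenotype vector (0/1 for binary traits, with the
#'   underlying liability in attribute `"liability"`).
#' @export
simulate_phenotype <- function(g, model, seed = 1L) {
  stopifnot(inherits(g, "genotype_set"), inherits(model, "trait_model"))
  if (length(model$causal_effects) != ncol(g$dosages))
    stop_ipw("causal_effects must have one entry per SNP")
  local_seeded(seed, {
    n <- nrow(g$dosages)
    gv <- as.numeric(g$dosages %*% model$causal_effects)
    gv <- gv - mean(gv)
    vg <- var(gv)
    h2 <- model$h2_target
    y <- if (h2 == 0 || vg == 0) {
      rnorm(n)
    } else {
      gv + rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
    }
    if (is.null(model$prevalence)) return(y)
    thr <- quantile(y, 1 - model$prevalence, names = FALSE)
    structure(as.numeric(y > thr), liability = y)
  })
}

#' Simulate the fourteen auxiliary variables from latent traits
#'
#' Continuous auxiliaries are linear-plus-noise in the (standardized) traits
#' and reported in natural units; categorical auxiliaries discretize a latent
#' Gaussian score at the quantiles of fixed marginal level probabilities, so
#' the declared level structure (counts 7, 2, 6, 3, 4, 5, 4, 3, 3) is
#' reproduced regardless of the loadings.
#'
#' @param phenotypes Numeric matrix (individuals x traits) or vector; traits
#'   are standardized internally before applying loadings.
#' @param loadings Numeric matrix with one row per auxiliary variable
#'   (rownames from [aux_spec()]) and one column per trait; entry (v, t) is
#'   the loading of trait t on variable v's latent score. Missing rows load
#'   zero.
#' @param seed Integer seed.
#' @param level_probs Optional named list overriding the default marginal
#'   level probabilities of the categorical variables.
#' @return Data frame with the 14 auxiliary columns (categoricals as factors
#'   with the declared levels).
#' @export
simulate_auxiliary <- function(phenotypes, loadings = NULL, seed = 1L,
                               level_probs = NULL) {
  ph <- as.matrix(phenotypes)
  n <- nrow(ph)
  ph <- scale(ph)
  ph[is.nan(ph)] <- 0
  spec <- aux_spec()
  probs <- aux_level_probs()
  if (!is.null(level_probs)) probs[names(level_probs)] <- level_probs
  L <- matrix(0, nrow(spec), ncol(ph), dimnames = list(spec$variable, NULL))
  if (!is.null(loadings)) {
    loadings <- as.matrix(loadings)
    unknown <- setdiff(rownames(loadings), spec$variable)
    if (length(unknown))
      stop_ipw("unknown auxiliary variable(s) in loadings: %s",
               paste(unknown, collapse = ", "))
    L[rownames(loadings), ] <- loadings
  }
  scales <- aux_continuous_scales()
  local_seeded(seed, {
    out <- vector("list", nrow(spec))
    names(out) <- spec$variable
    for (i in seq_len(nrow(spec))) {
      v <- spec$variable[i]
      latent <- as.numeric(ph %*% L[v, ]) + rnorm(n)
      # standardize the latent so level probabilities stay calibrated
      latent <- latent / sqrt(sum(L[v, ]^2) + 1)
      if (spec$type[i] == "continuous") {
        sc <- scales[scales$variable == v, ]
        out[[i]] <- sc$mean + sc$sd * latent
      } else {
        p <- probs[[v]]
        if (abs(sum(p) - 1) > 1e-8) stop_ipw("level probabilities for '%s' must sum to 1", v)
        cuts <- qnorm(cumsum(p))[-length(p)]
        out[[i]] <- factor(spec$levels[[i]][findInterval(latent, cuts) + 1L],
                           levels = spec$levels[[i]])
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Logistic participation mechanism
#'
#' @param coefficients Named numeric vector of logit-scale coefficients;
#'   applied to the standardized numeric coding of each variable (continuous
#'   as-is, categorical as level index). A name of the form `"a:b"` adds an
#'   interaction term, the product of the two standardized codings;
#'   interactions are what make participation depend jointly on two
#'   characteristics (e.g. educated *and* healthy volunteers), which is the
#'   mechanism that visibly distorts pairwise associations in the selected
#'   sample and motivates interaction terms in the weight model.
#' @param target_fraction Expected selected share in (0, 1); the intercept is
#'   solved numerically so the population mean participation probability
#'   equals it.
#' @param intercept Optional fixed intercept overriding the calibration.
#' @return A `participation_model` list.
#' @export
participation_model <- function(coefficients = numeric(0),
                                target_fraction = 0.055,
                                intercept = NULL) {
  assert_prob(target_fraction, "target_fraction")
  used <- if (length(coefficients))
    unlist(strsplit(names(coefficients), ":", fixed = TRUE)) else character(0)
  unknown <- setdiff(used, aux_variables())
  if (length(unknown))
    stop_ipw("unknown auxiliary variable(s): %s", paste(unknown, collapse = ", "))
  structure(list(coefficients = coefficients,
                 target_fraction = target_fraction,
                 intercept = intercept),
            class = "participation_model")
}

#' Apply a participation mechanism to a cohort
#'
#' Each individual is selected with probability
#' `plogis(intercept + sum(coef * z))` where `z` are the standardized numeric
#' codings of the auxiliary variables; the intercept is calibrated by root
#' finding so the expected selected fraction equals the model's
#' `target_fraction`. Selecting on a variable that is itself a consequence of
#' genotype and environment induces the collider structure that distorts
#' downstream associations.
#'
#' @param cohort Data frame containing the 14 auxiliary columns.
#' @param pm A [participation_model()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return `cohort` with columns `participation` (0/1) and `true_P` appended.
#' @export
apply_participation <- function(cohort, pm, seed = 1L) {
  stopifnot(inherits(pm, "participation_model"))
  z <- aux_numeric(cohort)
  if (anyNA(z)) stop_ipw("auxiliary profile incomplete")
  zs <- scale(z)
  zs[is.nan(zs)] <- 0
  lp <- rep(0, nrow(cohort))
  for (v in names(pm$coefficients)) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    x <- zs[, parts[1]]
    if (length(parts) == 2L) x <- x * zs[, parts[2]]
    lp <- lp + pm$coefficients[[v]] * x
  }
  if (!all(is.finite(lp))) stop_ipw("non-finite participation linear predictor")
  a <- pm$intercept
  if (is.null(a)) {
    f <- function(a) mean(plogis(a + lp)) - pm$target_fraction
    a <- uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
  }
  P <- plogis(a + lp)
  cohort$true_P <- P
  cohort$participation <- local_seeded(seed, rbinom(nrow(cohort), 1L, P))
  attr(cohort, "participation_intercept") <- a
  cohort
}

#' Draw a representative reference sample from a population
#'
#' Simple random sampling by default (all design weights 1). A stratified
#' scheme samples each stratum of a categorical auxiliary at a relative rate
#' and attaches design weights proportional to the inverse inclusion
#' probability, as survey reference samples supply them.
#'
#' @param population Cohort data frame (one row per population member).
#' @param n_ref Reference-sample size.
#' @param design_scheme `NULL` for simple random sampling, or
#'   `list(by = <variable>, rates = <named relative sampling rates per level>)`.
#' @param seed Integer seed.
#' @return The sampled rows with `participation = 0` and a `design_weight`
#'   column.
#' @export
draw_reference_sample <- function(population, n_ref, design_scheme = NULL,
                                  seed = 1L) {
  if (n_ref <= 0) stop_ipw("n_ref must be positive")
  if (n_ref > nrow(population)) stop_ipw("n_ref exceeds the population size")
  local_seeded(seed, {
    if (is.null(design_scheme)) {
      idx <- sample.int(nrow(population), n_ref)
      out <- population[idx, , drop = FALSE]
      out$design_weight <- 1
    } else {
      v <- design_scheme$by
      rates <- design_scheme$rates
      strat <- as.character(population[[v]])
      if (!all(strat %in% names(rates)))
        stop_ipw("design_scheme rates must cover every level of '%s'", v)
      # per-stratum sample sizes proportional to N_h * rate_h, scaled to n_ref
      Nh <- table(strat)
      target <- Nh * rates[names(Nh)]
      nh <- round(target / sum(target) * n_ref)
      nh <- pmin(pmax(nh, 1L), Nh)
      idx <- unlist(lapply(names(Nh), function(h) {
        sample(which(strat == h), nh[[h]])
      }), use.names = FALSE)
      out <- population[idx, , drop = FALSE]
      # inverse inclusion probability N_h / n_h
      wmap <- as.numeric(Nh) / as.numeric(nh)
      names(wmap) <- names(Nh)
      out$design_weight <- wmap[as.character(out[[v]])]
    }
    out$participation <- 0L
    rownames(out) <- NULL
    out
  })
}

#' Stack a selected cohort and a reference sample
#'
#' @param selected Cohort rows with `participation = 1` (design weight 1).
#' @param reference Reference rows from [draw_reference_sample()].
#' @return Stacked data frame with aligned columns; selected rows first.
#' @export
stack_cohorts <- function(selected, reference) {
  selected$participation <- 1L
  if (is.null(selected$design_weight)) selected$design_weight <- 1
  if (is.null(reference$design_weight)) reference$design_weight <- 1
  reference$participation <- 0L
  keep <- intersect(names(selected), names(reference))
  rbind(selected[, keep, drop = FALSE], reference[, keep, drop = FALSE])
}
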