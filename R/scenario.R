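#' Default "healthy-volunteer" simulation scenario
#'
#' Bundles every generator setting for a full synthetic study: a target
#' population with genotypes, two polygenic traits (an exposure with a causal
#' effect on an outcome, supporting Mendelian-randomization checks), the
#' fourteen auxiliary variables loaded on those traits, a logistic
#' participation mechanism with healthy-volunteer signs (positive selection
#' on education/health analogues, negative on smoking), and a representative
#' reference sample.
#'
#' Defaults encode the desk-scale study conditions the package emulates: a
#' population of 50,000 with a participation rate of 10% (about 5,000
#' volunteers) and a reference sample of 8,000. Selection loads on
#' education, overall health, smoking, age and adiposity, with its strongest
#' terms on pairwise interactions (educated *and* healthy people volunteer
#' disproportionately): under rare logistic selection, main effects mostly
#' shift means while interaction terms are what distort pairwise
#' associations, the signature of collider bias the weights must undo.
#'
#' @param n_population,n_snps,n_reference Problem sizes.
#' @param maf_range,ld_block_size,ld_rho Genotype panel settings, see
#'   [population_config()].
#' @param target_fraction Expected participation rate.
#' @param h2_exposure,h2_outcome Trait heritabilities.
#' @param causal_alpha True causal effect of the (standardized) exposure on
#'   the outcome, the MR estimand.
#' @param prop_causal Fraction of SNPs carrying nonzero effects per trait.
#' @param participation_coefficients Named logit-scale coefficients of the
#'   participation mechanism over auxiliary variables.
#' @param loadings Trait-to-auxiliary loading matrix (rows = auxiliary
#'   variables, columns = exposure, outcome); `NULL` uses the scenario
#'   default.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A `scenario_config` list accepted by [simulate_scenario()].
#' @export
scenario_config <- function(n_population = 50000L, n_snps = 5000L,
                            n_reference = 8000L,
                            maf_range = c(0.05, 0.5),
                            ld_block_size = 5L, ld_rho = c(0.1, 0.7),
                            target_fraction = 0.1,
                            h2_exposure = 0.4, h2_outcome = 0.3,
                            causal_alpha = 0.3, prop_causal = 0.3,
                            participation_coefficients = c(
                              education = 0.15, health = 0.12, smoking = -0.12,
                              age = 0.1, bmi = -0.08,
                              "education:health" = 0.5,
                              "education:smoking" = -0.5,
                              "age:health" = 0.5, "bmi:health" = -0.5,
                              "education:age" = 0.5, "smoking:health" = -0.5,
                              "income:health" = 0.45, "obesity:age" = -0.45),
                            loadings = NULL, seed = 1L) {
  if (is.null(loadings)) {
    loadings <- matrix(0, 14, 2,
                       dimnames = list(aux_variables(), c("exposure", "outcome")))
    loadings["education", "exposure"] <- 0.7
    loadings["income", "exposure"] <- 0.4
    loadings["health", "outcome"] <- 0.6
    loadings["bmi", "outcome"] <- -0.5
    loadings["obesity", "outcome"] <- -0.5
    loadings["smoking", "outcome"] <- -0.4
    loadings["smoking", "exposure"] <- -0.3
  }
  structure(list(n_population = as.integer(n_population),
                 n_snps = as.integer(n_snps),
                 n_reference = as.integer(n_reference),
                 maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho, target_fraction = target_fraction,
                 h2_exposure = h2_exposure, h2_outcome = h2_outcome,
                 causal_alpha = causal_alpha, prop_causal = prop_causal,
                 participation_coefficients = participation_coefficients,
                 loadings = loadings, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: genotypes, exposure and outcome traits (the
#' outcome receives `causal_alpha` times the standardized exposure on top of
#' its own genetic and environmental components), auxiliary variables,
#' participation, and the reference sample.
#'
#' @param config A [scenario_config()].
#' @return List with elements `genotypes` (`genotype_set`), `population`
#'   (cohort data frame with `id`, the 14 auxiliaries, `exposure`, `outcome`,
#'   `participation`, `true_P`), `selected`, `reference` and `stacked`
#'   cohort tables, `causal_effects` (list per trait) and `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  s <- config$seed
  g <- simulate_genotypes(population_config(
    config$n_population, config$n_snps, config$maf_range,
    config$ld_block_size, config$ld_rho, seed = s))
  m <- config$n_snps
  eff <- local_seeded(s + 11L, {
    n_causal <- max(1L, round(config$prop_causal * m))
    list(
      exposure = {
        b <- numeric(m); idx <- sample.int(m, n_causal)
        b[idx] <- rnorm(n_causal); b
      },
      outcome = {
        b <- numeric(m); idx <- sample.int(m, n_causal)
        b[idx] <- rnorm(n_causal); b
      }
    )
  })
  exposure <- simulate_phenotype(g, trait_model(eff$exposure, config$h2_exposure),
                                 seed = s + 21L)
  outcome_own <- simulate_phenotype(g, trait_model(eff$outcome, config$h2_outcome),
                                    seed = s + 22L)
  outcome <- config$causal_alpha * as.numeric(scale(exposure)) +
    as.numeric(scale(outcome_own))
  aux <- simulate_auxiliary(cbind(exposure = exposure, outcome = outcome),
                            config$loadings, seed = s + 31L)
  pop <- cbind(id = sprintf("ind%06d", seq_len(config$n_population)), aux,
               stringsAsFactors = FALSE)
  pop$exposure <- exposure
  pop$outcome <- outcome
  pm <- participation_model(config$participation_coefficients,
                            config$target_fraction)
  pop <- apply_participation(pop, pm, seed = s + 41L)
  selected <- pop[pop$participation == 1L, , drop = FALSE]
  selected$design_weight <- 1
  rownames(selected) <- NULL
  reference <- draw_reference_sample(pop, config$n_reference, seed = s + 51L)
  list(genotypes = g, population = pop, selected = selected,
       reference = reference,
       stacked = stack_cohorts(selected, reference),
       causal_effects = eff, config = config)
}
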