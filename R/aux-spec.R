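#' Schema of the harmonized auxiliary variables
#'
#' Participation weighting rests on a set of fourteen auxiliary variables that
#' can be harmonized between the selected cohort and the representative
#' reference sample: five continuous measures (age, body-mass index, weight,
#' height and age at completing full-time education) and nine categorical
#' measures (household size, sex, alcohol consumption frequency, smoking
#' status, employment status, income band, obesity status, overall health and
#' degree of urbanisation). This function returns the schema the package uses
#' everywhere a cohort table is consumed: variable names, types, and the fixed
#' level sets of the categorical variables (with level counts
#' 7, 2, 6, 3, 4, 5, 4, 3 and 3).
#'
#' @return A data frame with one row per auxiliary variable and columns
#'   `variable`, `type` (`"continuous"` or `"categorical"`) and `levels`
#'   (list column; `NULL` for continuous variables).
#' @examples
#' spec <- aux_spec()
#' sum(spec$type == "continuous")                     # 5
#' lengths(spec$levels[spec$type == "categorical"])   # 7 2 6 3 4 5 4 3 3
#' @export
aux_spec <- function() {
  lv <- list(
    household_size = c("1", "2", "3", "4", "5", "6", "7+"),
    sex            = c("male", "female"),
    alcohol        = c("never", "few_per_year", "monthly", "weekly_1_2",
                       "weekly_3_4", "daily"),
    smoking        = c("never", "previous", "current"),
    employment     = c("employed", "inactive", "retired", "unemployed"),
    income         = c("<18k", "18k-31k", "31k-52k", "52k-100k", ">100k"),
    obesity        = c("underweight", "healthy", "overweight", "obese"),
    health         = c("poor", "fair", "good"),
    urbanisation   = c("village", "town", "urban")
  )
  cont <- c("age", "bmi", "weight", "height", "education")
  data.frame(
    variable = c(cont, names(lv)),
    type = c(rep("continuous", length(cont)), rep("categorical", length(lv))),
    levels = I(c(rep(list(NULL), length(cont)), unname(lv))),
    stringsAsFactors = FALSE
  )
}

# Location/scale used to express the continuous auxiliaries in natural units.
aux_continuous_scales <- function() {
  data.frame(
    variable = c("age", "bmi", "weight", "height", "education"),
    mean = c(55, 27, 78, 169, 17),
    sd = c(8, 4.5, 15, 9, 2.5)
  )
}

# Default marginal level probabilities for the categorical auxiliaries.
aux_level_probs <- function() {
  list(
    household_size = c(0.14, 0.36, 0.16, 0.18, 0.09, 0.04, 0.03),
    sex            = c(0.50, 0.50),
    alcohol        = c(0.12, 0.12, 0.12, 0.26, 0.20, 0.18),
    smoking        = c(0.45, 0.35, 0.20),
    employment     = c(0.55, 0.15, 0.25, 0.05),
    income         = c(0.25, 0.25, 0.25, 0.18, 0.07),
    obesity        = c(0.01, 0.34, 0.40, 0.25),
    health         = c(0.15, 0.25, 0.60),
    urbanisation   = c(0.12, 0.20, 0.68)
  )
}

aux_variables <- function() aux_spec()$variable

# Numeric coding of a cohort's auxiliary columns: continuous variables as-is,
# categorical variables as their (ordered) level index. Used for correlation
# summaries and the participation mechanism's linear predictor.
aux_numeric <- function(cohort, spec = aux_spec()) {
  out <- matrix(NA_real_, nrow(cohort), nrow(spec),
                dimnames = list(NULL, spec$variable))
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    if (!v %in% names(cohort)) stop_ipw("cohort lacks auxiliary column '%s'", v)
    x <- cohort[[v]]
    if (spec$type[i] == "continuous") {
      out[, i] <- as.numeric(x)
    } else {
      f <- factor(as.character(x), levels = spec$levels[[i]])
      if (anyNA(f) && !anyNA(x))
        stop_ipw("variable '%s' contains levels outside its declared set", v)
      out[, i] <- as.integer(f)
    }
  }
  out
}
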