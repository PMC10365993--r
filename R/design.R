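#' Build the participation-model design matrix
#'
#' Expands the fourteen auxiliary variables into main effects and all
#' pairwise interactions. Continuous variables enter as-is; every level of
#' every categorical variable gets its own 0/1 indicator (no reference level
#' is dropped). All unordered pairs of distinct main-effect columns are then
#' appended as product columns, including products of two indicators of the
#' same variable, which are identically zero (mutually exclusive levels) and
#' left for the LASSO to discard. With the default variable set this yields
#' 5 + 37 = 42 main-effect columns and choose(42, 2) = 861 products, 903
#' columns in total.
#'
#' @param cohort Stacked cohort data frame containing the auxiliary columns.
#'   Rows with missing auxiliary values must be dropped beforehand (no
#'   imputation is performed; an error is raised if any remain).
#' @param spec Auxiliary schema, by default [aux_spec()].
#' @return A sparse `dgCMatrix` (rows = cohort rows) with deterministic
#'   column naming `var`, `var=level` and `a:b` for products, and attributes
#'   `n_main` and `main_names`.
#' @examples
#' coh <- simulate_auxiliary(matrix(rnorm(50), 50, 1), seed = 1)
#' X <- build_design(coh)
#' ncol(X)  # 903
#' @export
build_design <- function(cohort, spec = aux_spec()) {
  need <- setdiff(spec$variable, names(cohort))
  if (length(need))
    stop_ipw("cohort lacks auxiliary column(s): %s", paste(need, collapse = ", "))
  aux <- cohort[, spec$variable, drop = FALSE]
  if (anyNA(aux))
    stop_ipw("auxiliary values contain missing data; drop those rows first")
  n <- nrow(aux)
  cols <- list()
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    if (spec$type[i] == "continuous") {
      cols[[v]] <- as.numeric(aux[[v]])
    } else {
      levs <- spec$levels[[i]]
      x <- as.character(aux[[v]])
      bad <- setdiff(unique(x), levs)
      if (length(bad))
        stop_ipw("variable '%s' has unseen level(s): %s", v,
                 paste(bad, collapse = ", "))
      for (l in levs) cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
    }
  }
  mains <- do.call(cbind, cols)
  colnames(mains) <- names(cols)
  k <- ncol(mains)
  pairs <- combn(k, 2)
  prod_mat <- mains[, pairs[1, ], drop = FALSE] * mains[, pairs[2, ], drop = FALSE]
  colnames(prod_mat) <- paste(colnames(mains)[pairs[1, ]],
                              colnames(mains)[pairs[2, ]], sep = ":")
  X <- Matrix::Matrix(cbind(mains, prod_mat), sparse = TRUE)
  attr(X, "n_main") <- k
  attr(X, "main_names") <- colnames(mains)
  X
}
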