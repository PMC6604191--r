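#' Per-cohort epigenome-wide association of an exposure with methylation
#'
#' Fits, for every CpG in the cohort, an ordinary least squares
#' regression of methylation (beta values, untransformed) on the
#' exposure plus covariates, and reports the exposure coefficient with
#' its standard error and a two-sided p-value from the t distribution
#' with residual degrees of freedom. Complete cases are used; CpGs with
#' zero variance among complete cases are skipped with a message.
#'
#' @param bundle A `cohort_bundle` (see [simulate_cohort()] or
#'   [read_cohort_bundle()]).
#' @param exposure_column Name of the exposure column in the covariate
#'   table (e.g. `"maternal_smoking"`).
#' @param covariate_columns Character vector of adjustment covariates
#'   (column names in the covariate table). Cell-type proportions sum to
#'   one, so include at most `k - 1` of them alongside an intercept.
#' @param model_tag Label stored with each record identifying the model
#'   variant.
#' @return A tibble with one row per analyzed CpG: `cpg_id`, `beta`,
#'   `se`, `pval`, `n`, `model_tag`.
#' @export
fit_ewas <- function(bundle, exposure_column = "maternal_smoking",
                     covariate_columns = character(),
                     model_tag = "main") {
  check_bundle(bundle)
  d <- build_design(bundle$covariates, exposure_column, covariate_columns)
  Y <- bundle$methylation[d$complete, , drop = FALSE]
  keep <- apply(Y, 2, function(col) var(col) > 0)
  if (any(!keep)) {
    inform(sprintf("skipping %d zero-variance CpG%s: %s.",
                   sum(!keep), if (sum(!keep) > 1L) "s" else "",
                   paste(head(colnames(Y)[!keep], 5L), collapse = ", ")))
  }
  Y <- Y[, keep, drop = FALSE]
  if (ncol(Y) == 0L) abort("no CpG with non-zero variance to analyze.")
  fit <- ols_many(d$X, Y, focal = exposure_column)
  tibble::tibble(
    cpg_id = colnames(Y),
    beta = fit$beta,
    se = fit$se,
    pval = fit$pval,
    n = fit$n,
    model_tag = model_tag
  )
}

check_bundle <- function(bundle) {
  if (!inherits(bundle, "cohort_bundle")) {
    abort("`bundle` must be a cohort_bundle.")
  }
  if (!identical(rownames(bundle$methylation),
                 bundle$covariates$sample_id)) {
    abort("sample sets of methylation matrix and covariate table differ.")
  }
  invisible(bundle)
}

#' Restrict a cohort to offspring who never smoked regularly
#'
#' Subsets the cohort to individuals with `own_smoking == 0`. The
#' own-smoking covariate should then be dropped from subsequent models,
#' since it is constant in the subset.
#'
#' @param bundle A `cohort_bundle` whose covariates include
#'   `own_smoking`.
#' @return A `cohort_bundle` containing only never-smokers.
#' @export
restrict_never_smokers <- function(bundle) {
  check_bundle(bundle)
  assert_columns(bundle$covariates, "own_smoking", "covariate table")
  keep <- bundle$covariates$own_smoking == 0
  if (!any(keep)) abort("no never-smokers in the cohort; empty subset.")
  subset_bundle(bundle, keep)
}

subset_bundle <- function(bundle, keep) {
  structure(
    list(
      methylation = bundle$methylation[keep, , drop = FALSE],
      annotation = bundle$annotation,
      covariates = bundle$covariates[keep, , drop = FALSE],
      timepoint = bundle$timepoint,
      internals = NULL
    ),
    class = "cohort_bundle"
  )
}

#' Dose-response association of smoking intensity with methylation
#'
#' Regresses per-CpG standardized methylation (zero mean, unit SD) on
#' the number of cigarettes smoked per day during pregnancy plus
#' covariates, over the full cohort including unexposed (dose 0)
#' mothers. The per-cigarette slope and its standard error are scaled by
#' 3, so reported effects are in standard deviation units of methylation
#' per three additional cigarettes per day.
#'
#' @inheritParams fit_ewas
#' @param dose_column Name of the cigarettes/day column.
#' @return A tibble of records as in [fit_ewas()], with `model_tag`
#'   `"dose_response"` and effects in SD units per 3 cigarettes/day.
#' @export
fit_dose_response <- function(bundle, covariate_columns = character(),
                              dose_column = "cigs_per_day") {
  check_bundle(bundle)
  assert_columns(bundle$covariates, dose_column, "covariate table")
  dose <- bundle$covariates[[dose_column]]
  if (length(unique(dose[is.finite(dose)])) < 2L) {
    abort(sprintf("dose column '%s' has zero variance.", dose_column))
  }
  d <- build_design(bundle$covariates, dose_column, covariate_columns)
  Y <- bundle$methylation[d$complete, , drop = FALSE]
  sds <- apply(Y, 2, sd)
  keep <- sds > 0
  if (any(!keep)) {
    inform(sprintf("skipping %d zero-variance CpG(s).", sum(!keep)))
  }
  Y <- scale(Y[, keep, drop = FALSE])
  fit <- ols_many(d$X, Y, focal = dose_column)
  tibble::tibble(
    cpg_id = colnames(Y),
    beta = 3 * fit$beta,
    se = 3 * fit$se,
    pval = fit$pval,
    n = fit$n,
    model_tag = "dose_response"
  )
}

#' Negative-control comparison of maternal and paternal smoking
#'
#' Fits three models per CpG: methylation on maternal smoking (plus
#' covariates), on paternal smoking, and on maternal smoking adjusted
#' additionally for paternal smoking. Under the negative-control
#' assumption -- paternal smoking shares the confounding structure of
#' maternal smoking but has no intrauterine biological path -- similar
#' effect sizes for the two exposures indicate confounding, while
#' substantially smaller paternal effects support a direct intrauterine
#' effect.
#'
#' @inheritParams fit_ewas
#' @param maternal_column,paternal_column Exposure column names.
#' @return A tibble of records as in [fit_ewas()] stacked over the three
#'   model variants, with `model_tag` one of `"maternal"`, `"paternal"`,
#'   `"maternal_adj_paternal"`.
#' @export
fit_negative_control <- function(bundle, covariate_columns = character(),
                                 maternal_column = "maternal_smoking",
                                 paternal_column = "paternal_smoking") {
  check_bundle(bundle)
  assert_columns(bundle$covariates, c(maternal_column, paternal_column),
                 "covariate table")
  pat <- bundle$covariates[[paternal_column]]
  if (length(unique(pat)) < 2L) {
    abort(sprintf("paternal indicator '%s' is constant; negative control %s",
                  paternal_column, "is uninformative."))
  }
  mat <- bundle$covariates[[maternal_column]]
  if (abs(cor(mat, pat)) >= 1 - 1e-12) {
    abort("maternal and paternal smoking are perfectly collinear; the negative control is uninformative.")
  }
  dplyr::bind_rows(
    fit_ewas(bundle, maternal_column, covariate_columns,
             model_tag = "maternal"),
    fit_ewas(bundle, paternal_column, covariate_columns,
             model_tag = "paternal"),
    fit_ewas(bundle, maternal_column,
             unique(c(covariate_columns, paternal_column)),
             model_tag = "maternal_adj_paternal")
  )
}
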