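#' @importFrom generics tidy glance
NULL

#' Tidy a mediation fit or record
#'
#' `tidy()` returns one row per estimated quantity with its interval
#' and p-value; `glance()` returns a one-row model summary.
#'
#' @param x A `mediation_fit` or `mediation_record`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mediation_record <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total_effect", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total_effect, x$prop_mediated),
    ci_lower = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1],
                 x$prop_mediated_ci[1]),
    ci_upper = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2],
                 x$prop_mediated_ci[2]),
    p.value = c(x$acme_pval, x$ade_pval, x$total_pval, NA_real_)
  )
}

#' @rdname tidy.mediation_record
#' @export
glance.mediation_record <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_draws = x$n_draws, seed = x$seed,
    outcome_model = x$outcome_model
  )
}

#' @rdname tidy.mediation_record
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta_a", "beta_b", "direct_effect", "total_effect"),
    estimate = c(x$beta_a, x$beta_b, x$direct_effect_coef,
                 x$total_effect_coef)
  )
}

#' @rdname tidy.mediation_record
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, outcome_model = x$outcome_model,
                 n_covariates = length(x$covariates))
}
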