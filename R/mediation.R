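#' Fit the mediator and outcome models for causal mediation
#'
#' Fits (i) the mediator model, CpG methylation on exposure plus
#' covariates, by OLS; (ii) the outcome model, outcome on exposure,
#' mediator, and covariates, by OLS (linear) or maximum-likelihood
#' logistic regression; and (iii) the total-effect model, outcome on
#' exposure and covariates without the mediator. Robust (sandwich)
#' coefficient covariances are stored for the quasi-Bayesian simulation.
#'
#' By convention the total effect comes from the mediator-free model and
#' the direct effect from the mediator-containing model; in the fully
#' linear case total - direct equals the product of the
#' exposure -> mediator and mediator -> outcome coefficients.
#'
#' @param data A data frame with one row per individual.
#' @param exposure,mediator,outcome Column names.
#' @param covariates Character vector of adjustment covariate columns.
#' @param outcome_model `"linear"` or `"logistic"`.
#' @param robust_type `vcovHC` flavor for the sandwich covariance
#'   (default `"HC3"`; `"classical"` uses the model-based covariance).
#' @return An object of class `mediation_fit`.
#' @export
fit_mediation_models <- function(data, exposure, mediator, outcome,
                                 covariates = character(),
                                 outcome_model = c("linear", "logistic"),
                                 robust_type = "HC3") {
  outcome_model <- match.arg(outcome_model)
  data <- tibble::as_tibble(data)
  assert_columns(data, c(exposure, mediator, outcome, covariates), "`data`")
  cols <- unique(c(exposure, mediator, outcome, covariates))
  dat <- as.data.frame(data[, cols, drop = FALSE])
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(cols) + 3L) {
    abort("too few complete cases for the mediation models.")
  }
  if (var(dat[[mediator]]) == 0) {
    abort(sprintf("mediator '%s' has zero variance.", mediator))
  }

  f_med <- stats::reformulate(c(exposure, covariates), response = mediator)
  f_out <- stats::reformulate(c(exposure, mediator, covariates),
                              response = outcome)
  f_tot <- stats::reformulate(c(exposure, covariates), response = outcome)

  m_med <- lm(f_med, data = dat)
  if (outcome_model == "linear") {
    m_out <- lm(f_out, data = dat)
    m_tot <- lm(f_tot, data = dat)
  } else {
    if (!all(dat[[outcome]] %in% c(0, 1))) {
      abort("logistic outcome model requires a 0/1 outcome.")
    }
    m_out <- glm(f_out, data = dat, family = binomial())
    if (!m_out$converged) abort("logistic outcome model did not converge.")
    fv <- fitted(m_out)
    if (any(fv < 1e-10) || any(fv > 1 - 1e-10)) {
      abort("(quasi-)separation detected in the logistic outcome model.")
    }
    m_tot <- glm(f_tot, data = dat, family = binomial())
  }
  vc <- function(m) {
    if (identical(robust_type, "classical")) vcov(m)
    else sandwich::vcovHC(m, type = robust_type)
  }
  structure(
    list(
      mediator_model = m_med,
      outcome_model_fit = m_out,
      total_model = m_tot,
      vcov_mediator = vc(m_med),
      vcov_outcome = vc(m_out),
      sigma_mediator = summary(m_med)$sigma,
      exposure = exposure, mediator = mediator, outcome = outcome,
      covariates = covariates, outcome_model = outcome_model,
      data = dat, n = nrow(dat),
      beta_a = unname(coef(m_med)[exposure]),
      beta_b = unname(coef(m_out)[mediator]),
      direct_effect_coef = unname(coef(m_out)[exposure]),
      total_effect_coef = unname(coef(m_tot)[exposure])
    ),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "<mediation_fit> %s outcome model, n = %d\n  exposure->mediator a = %.4g; mediator->outcome b = %.4g\n  direct = %.4g; total (mediator-free model) = %.4g\n",
    x$outcome_model, x$n, x$beta_a, x$beta_b,
    x$direct_effect_coef, x$total_effect_coef
  ))
  invisible(x)
}

#' Quasi-Bayesian Monte Carlo mediation
#'
#' Draws coefficient vectors from the normal approximation to the
#' sampling distribution of the fitted mediator and outcome models
#' (robust covariance) and computes, per draw, the average causal
#' mediation effect (ACME: the outcome change when the mediator moves
#' from its value under no exposure to its value under exposure, with
#' exposure held fixed, averaged over both exposure arms), the average
#' direct effect (ADE), and the total effect. For linear outcome models
#' without an exposure-mediator interaction these reduce per draw to the
#' product-of-coefficients and the identity ACME + ADE = TE holds
#' exactly; for logistic models the contrasts are computed on the
#' probability scale by simulating mediator values around the predicted
#' means. Point estimates are means over draws, intervals are 2.5/97.5
#' percentiles, and p-values are two-sided simulation tail
#' probabilities.
#'
#' @param fit A `mediation_fit`.
#' @param n_draws Number of coefficient draws (default 2000).
#' @param seed Integer seed; the record is reproducible given it.
#' @return An object of class `mediation_record`: point estimates,
#'   intervals and simulation p-values for ACME, ADE and total effect,
#'   the proportion mediated (per-draw median ratio, see
#'   [proportion_mediated()]), and the raw draws.
#' @export
quasi_bayesian_mediate <- function(fit, n_draws = 2000, seed = 1L) {
  if (!inherits(fit, "mediation_fit")) {
    abort("`fit` must come from fit_mediation_models().")
  }
  n_draws <- assert_count(n_draws, "n_draws", minimum = 100L)
  seed <- assert_count(seed, "seed", minimum = 0L)
  ok <- function(V) all(is.finite(V)) &&
    min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) > -1e-10
  if (!ok(fit$vcov_mediator) || !ok(fit$vcov_outcome)) {
    abort("singular or non-finite coefficient covariance; cannot simulate.")
  }
  with_seed(seed, {
    a_draws <- MASS::mvrnorm(n_draws, coef(fit$mediator_model),
                             fit$vcov_mediator)
    b_draws <- MASS::mvrnorm(n_draws, coef(fit$outcome_model_fit),
                             fit$vcov_outcome)
    exposure <- fit$exposure
    mediator <- fit$mediator

    if (fit$outcome_model == "linear") {
      # no interaction term: effects are covariate-free products
      acme <- a_draws[, exposure] * b_draws[, mediator]
      ade <- b_draws[, exposure]
      te <- acme + ade
    } else {
      dat <- fit$data
      n <- nrow(dat)
      Xm <- model.matrix(stats::delete.response(
        stats::terms(fit$mediator_model)), dat)
      Xy <- model.matrix(stats::delete.response(
        stats::terms(fit$outcome_model_fit)), dat)
      # linear predictors with exposure and mediator columns zeroed,
      # handled via rank-1 updates below
      am <- a_draws[, colnames(Xm), drop = FALSE]
      by <- b_draws[, colnames(Xy), drop = FALSE]
      Xm0 <- Xm; Xm0[, exposure] <- 0
      mu_base <- Xm0 %*% t(am)                       # n x draws
      mu0 <- mu_base
      mu1 <- mu_base + outer(rep(1, n), a_draws[, exposure])
      err <- rnorm(n, 0, fit$sigma_mediator)
      m0 <- mu0 + err
      m1 <- mu1 + err
      Xy0 <- Xy; Xy0[, exposure] <- 0; Xy0[, mediator] <- 0
      eta_base <- Xy0 %*% t(by)                      # n x draws
      bt <- outer(rep(1, n), b_draws[, exposure])
      bm <- matrix(b_draws[, mediator], n, n_draws, byrow = TRUE)
      p <- function(t, m) plogis(eta_base + t * bt + bm * m)
      acme <- 0.5 * colMeans(p(1, m1) - p(1, m0)) +
        0.5 * colMeans(p(0, m1) - p(0, m0))
      ade <- 0.5 * colMeans(p(1, m1) - p(0, m1)) +
        0.5 * colMeans(p(1, m0) - p(0, m0))
      te <- colMeans(p(1, m1) - p(0, m0))
    }

    summarize <- function(d) {
      ci <- quantile(d, c(0.025, 0.975), names = FALSE)
      pv <- 2 * min(mean(d <= 0), mean(d >= 0))
      list(est = mean(d), lo = ci[1], hi = ci[2], p = min(pv, 1))
    }
    s_acme <- summarize(acme)
    s_ade <- summarize(ade)
    s_te <- summarize(te)
    prop <- prop_mediated_from_draws(acme, te)

    structure(
      list(
        acme = s_acme$est, acme_ci = c(s_acme$lo, s_acme$hi),
        acme_pval = s_acme$p,
        ade = s_ade$est, ade_ci = c(s_ade$lo, s_ade$hi),
        ade_pval = s_ade$p,
        total_effect = s_te$est, total_ci = c(s_te$lo, s_te$hi),
        total_pval = s_te$p,
        prop_mediated = prop$estimate,
        prop_mediated_ci = c(prop$lo, prop$hi),
        n_draws = n_draws, seed = seed,
        outcome_model = fit$outcome_model, n = fit$n,
        draws = tibble::tibble(acme = acme, ade = ade, total_effect = te)
      ),
      class = "mediation_record"
    )
  })
}

prop_mediated_from_draws <- function(acme, te) {
  ratio <- acme / te
  ci <- quantile(ratio, c(0.025, 0.975), names = FALSE)
  list(estimate = stats::median(ratio), lo = ci[1], hi = ci[2],
       ratio_of_means = mean(acme) / mean(te))
}

#' @export
print.mediation_record <- function(x, ...) {
  fmt <- function(e, ci, p) {
    sprintf("%8.4f [%8.4f, %8.4f]  p = %.3g", e, ci[1], ci[2], p)
  }
  cat(sprintf("<mediation_record> %s outcome, %d draws, n = %d\n",
              x$outcome_model, x$n_draws, x$n))
  cat("  ACME :", fmt(x$acme, x$acme_ci, x$acme_pval), "\n")
  cat("  ADE  :", fmt(x$ade, x$ade_ci, x$ade_pval), "\n")
  cat("  Total:", fmt(x$total_effect, x$total_ci, x$total_pval), "\n")
  cat(sprintf("  Proportion mediated: %.3f [%.3f, %.3f]\n",
              x$prop_mediated, x$prop_mediated_ci[1],
              x$prop_mediated_ci[2]))
  invisible(x)
}

#' Proportion of the total effect explained by the mediator
#'
#' Computed per simulation draw as ACME / total effect and summarized
#' by the median with a percentile interval (ratios of means are
#' unstable when the total effect is small; the mean-of-ratios median
#' is the primary summary, and the ratio of mean ACME to mean total
#' effect is also reported). An instability flag is raised when the
#' total-effect interval covers zero, in which case the ratio draws mix
#' signs and the proportion is not interpretable.
#'
#' @param record A `mediation_record` from [quasi_bayesian_mediate()].
#' @return A one-row tibble: `prop_mediated`, `ci_lower`, `ci_upper`,
#'   `ratio_of_means`, `unstable`.
#' @export
proportion_mediated <- function(record) {
  if (!inherits(record, "mediation_record")) {
    abort("`record` must come from quasi_bayesian_mediate().")
  }
  if (record$total_effect == 0) {
    abort("total effect is exactly zero; proportion mediated undefined.")
  }
  d <- record$draws
  pr <- prop_mediated_from_draws(d$acme, d$total_effect)
  unstable <- (record$total_ci[1] <= 0 && record$total_ci[2] >= 0) ||
    sign(record$acme) * sign(record$total_effect) < 0
  tibble::tibble(
    prop_mediated = pr$estimate,
    ci_lower = pr$lo,
    ci_upper = pr$hi,
    ratio_of_means = pr$ratio_of_means,
    unstable = unstable
  )
}
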