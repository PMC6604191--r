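test_that("EWAS matches the normal-equations oracle on a toy cohort", {
  b <- toy_bundle()
  rec <- fit_ewas(b, "maternal_smoking", c("sex", "bmi"))
  X <- cbind(1, b$covariates$maternal_smoking, b$covariates$sex,
             b$covariates$bmi)
  colnames(X) <- c("(Intercept)", "maternal_smoking", "sex", "bmi")
  for (cg in colnames(b$methylation)) {
    oracle <- ols_oracle(X, b$methylation[, cg], "maternal_smoking")
    row <- rec[rec$cpg_id == cg, ]
    expect_equal(row$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(row$se, oracle$se, tolerance = 1e-10)
    expect_equal(row$pval, oracle$pval, tolerance = 1e-10)
  }
  expect_true(all(rec$n == 6))
})

test_that("a planted noiseless effect is recovered exactly", {
  sim <- simulate_cohort(noiseless_config(n_samples = 100, n_cpgs = 3,
                                          effect_sizes = c(cpg_1 = 0.05)))
  rec <- fit_ewas(sim$bundle)
  expect_equal(rec$beta[rec$cpg_id == "cpg_1"], 0.05, tolerance = 1e-12)
})

test_that("stored p-values regenerate from beta/se and the residual df", {
  sim <- planted_sim(n = 150, seed = 4)
  rec <- fit_ewas(sim$bundle, covariate_columns = c("sex", "bmi"))
  df <- 150 - 4
  expect_equal(rec$pval, 2 * pt(-abs(rec$beta / rec$se), df),
               tolerance = 1e-12)
})

test_that("an orthogonal covariate leaves noiseless estimates unchanged", {
  b <- toy_bundle()
  # construct methylation exactly linear in exposure, no noise
  meth <- outer(b$covariates$maternal_smoking, c(0.05, -0.02, 0.01)) + 0.4
  dimnames(meth) <- dimnames(b$methylation)
  b2 <- cohort_bundle(meth, b$annotation, b$covariates)
  base <- fit_ewas(b2, "maternal_smoking")
  # a covariate orthogonal to the exposure (balanced within groups)
  b2$covariates$orth <- c(-1, 1, 0, -1, 1, 0)
  with_orth <- fit_ewas(b2, "maternal_smoking", "orth")
  expect_equal(base$beta, with_orth$beta, tolerance = 1e-8)
})

test_that("EWAS error contracts: rank deficiency, constants, zero variance", {
  b <- toy_bundle()
  b$covariates$dup <- b$covariates$maternal_smoking
  expect_error(fit_ewas(b, "maternal_smoking", "dup"), "rank deficient")
  b2 <- toy_bundle()
  b2$covariates$konst <- 1
  expect_error(fit_ewas(b2, "maternal_smoking", "konst"), "konst")
  b3 <- toy_bundle()
  b3$methylation[, "cpg_2"] <- 0.5
  expect_message(rec <- fit_ewas(b3, "maternal_smoking"), "zero-variance")
  expect_false("cpg_2" %in% rec$cpg_id)
})

test_that("never-smoker restriction subsets and then matches the full analysis", {
  b <- toy_bundle()  # 2 of 6 smoke themselves
  ns <- restrict_never_smokers(b)
  expect_equal(nrow(ns$covariates), 4)
  expect_true(all(ns$covariates$own_smoking == 0))
  expect_identical(rownames(ns$methylation), ns$covariates$sample_id)
  # all never-smokers: identity on samples
  b2 <- toy_bundle()
  b2$covariates$own_smoking <- 0L
  expect_identical(restrict_never_smokers(b2)$covariates$sample_id,
                   b2$covariates$sample_id)
  # none left: rejected
  b3 <- toy_bundle()
  b3$covariates$own_smoking <- 1L
  expect_error(restrict_never_smokers(b3), "empty")
})

test_that("never-smoker estimates agree with the full analysis when own smoking is inert", {
  # own smoking carries no methylation effect in the generator, so the
  # subset analysis must be concordant with the full analysis
  n_seeds <- 50
  agree <- vapply(seq_len(n_seeds), function(s) {
    sim <- planted_sim(n = 400, effect = 0.04, seed = s)
    full <- fit_ewas(sim$bundle, covariate_columns = c("sex", "own_smoking"))
    nsb <- restrict_never_smokers(sim$bundle)
    sub <- fit_ewas(nsb, covariate_columns = "sex")
    f <- full[full$cpg_id == "cpg_1", ]
    g <- sub[sub$cpg_id == "cpg_1", ]
    abs(f$beta - g$beta) <= 1.96 * sqrt(f$se^2 + g$se^2)
  }, logical(1))
  expect_gte(mean(agree), 0.90)
})

test_that("dose-response reports SD units per three cigarettes per day", {
  # noiseless: methylation = 0.4 + 0.01 * cigs exactly
  b <- toy_bundle()
  meth <- matrix(0.4 + 0.01 * b$covariates$cigs_per_day, ncol = 1,
                 dimnames = list(b$covariates$sample_id, "cpg_1"))
  ann <- b$annotation[1, ]
  b2 <- cohort_bundle(meth, ann, b$covariates)
  rec <- fit_dose_response(b2)
  # slope on standardized methylation is 1/sd(meth) per cigarette, x3
  expect_equal(rec$beta, 3 * 0.01 / sd(meth), tolerance = 1e-10)
  expect_equal(rec$model_tag, "dose_response")
  # all doses zero rejected
  b3 <- toy_bundle()
  b3$covariates$cigs_per_day <- 0
  expect_error(fit_dose_response(b3), "zero variance")
})

test_that("dose-response slope recovery over repeated simulations", {
  slope <- 0.01  # beta units per cigarette
  est <- vapply(1:50, function(s) {
    sim <- simulate_cohort(sim_config(
      n_samples = 500, n_cpgs = 2, dose_slopes = c(cpg_1 = slope),
      noise_sd = 0.05, covariate_loading_sd = 0, cell_loading_sd = 0,
      seed = s
    ))
    rec <- fit_dose_response(sim$bundle)
    sd_m <- sd(sim$bundle$methylation[, "cpg_1"])
    # convert back to beta-value units per 3 cigarettes
    rec$beta[rec$cpg_id == "cpg_1"] * sd_m
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 3 * slope), 3 * mc_se)
})

test_that("paternal negative control shows attenuated effects under shared environment", {
  n_seeds <- 50
  smaller <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_cohort(sim_config(
      n_samples = 400, n_cpgs = 3,
      effect_sizes = c(cpg_1 = 0.05, cpg_2 = 0.03),
      paternal_shared_env_corr = 0.5, seed = s
    ))
    nc <- fit_negative_control(sim$bundle, c("sex", "bmi"))
    planted <- c("cpg_1", "cpg_2")
    m <- mean(abs(nc$beta[nc$model_tag == "maternal" &
                            nc$cpg_id %in% planted]))
    p <- mean(abs(nc$beta[nc$model_tag == "paternal" &
                            nc$cpg_id %in% planted]))
    p < m
  }, logical(1))
  expect_gte(mean(smaller), 0.95)
})

test_that("paternal adjustment is inert when the exposures are independent", {
  sim <- simulate_cohort(noiseless_config(
    n_samples = 300, n_cpgs = 2, effect_sizes = c(cpg_1 = 0.05),
    paternal_shared_env_corr = 0
  ))
  nc <- fit_negative_control(sim$bundle)
  mat <- nc[nc$model_tag == "maternal", ]
  adj <- nc[nc$model_tag == "maternal_adj_paternal", ]
  expect_equal(mat$beta, adj$beta, tolerance = 1e-6)
  # constant paternal indicator rejected
  b <- toy_bundle()
  b$covariates$paternal_smoking <- 0L
  expect_error(fit_negative_control(b), "constant")
})
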