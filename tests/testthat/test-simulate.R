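test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 50, n_cpgs = 10,
                    effect_sizes = c(cpg_2 = 0.03), seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$bundle$methylation, b$bundle$methylation)
  expect_identical(a$bundle$covariates, b$bundle$covariates)
  expect_identical(a$truth$cpg, b$truth$cpg)
  # and the serialized form round-trips byte-identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_bundle(a$bundle, d1)
  write_cohort_bundle(b$bundle, d2)
  expect_identical(readLines(file.path(d1, "t1_methylation.tsv")),
                   readLines(file.path(d2, "t1_methylation.tsv")))
})

test_that("noiseless generative identities hold exactly", {
  cfg <- noiseless_config(n_samples = 80, n_cpgs = 3,
                          effect_sizes = c(cpg_1 = 0.05))
  sim <- simulate_cohort(cfg)
  expo <- sim$bundle$covariates$maternal_smoking
  diffs <- colMeans(sim$bundle$methylation[expo == 1, , drop = FALSE]) -
    colMeans(sim$bundle$methylation[expo == 0, , drop = FALSE])
  expect_equal(unname(diffs["cpg_1"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(diffs["cpg_2"]), 0, tolerance = 1e-12)
  # paternal smoking has zero direct effect: within the maternal-unexposed
  # (and dose-zero) stratum, the paternal contrast is exactly zero
  pat <- sim$bundle$covariates$paternal_smoking
  sub <- expo == 0
  pd <- colMeans(sim$bundle$methylation[sub & pat == 1, , drop = FALSE]) -
    colMeans(sim$bundle$methylation[sub & pat == 0, , drop = FALSE])
  expect_equal(unname(pd), rep(0, 3), tolerance = 1e-12)
})

test_that("empirical exposure prevalence matches the configured rate", {
  cfg <- sim_config(n_samples = 2000, n_cpgs = 2, seed = 5)
  sim <- simulate_cohort(cfg)
  phat <- mean(sim$bundle$covariates$maternal_smoking)
  se3 <- 3 * sqrt(0.16 * 0.84 / 2000)
  expect_lt(abs(phat - 0.16), se3)
  # cigarettes/day: zero for unexposed, >= 1 for exposed
  cigs <- sim$bundle$covariates$cigs_per_day
  expo <- sim$bundle$covariates$maternal_smoking
  expect_true(all(cigs[expo == 0] == 0))
  expect_true(all(cigs[expo == 1] >= 1))
  # cell proportions simplex-valid
  cp <- as.matrix(sim$bundle$covariates[, grep("^cell_prop_",
    names(sim$bundle$covariates))])
  expect_true(all(cp >= 0))
  expect_equal(rowSums(cp), rep(1, 2000), tolerance = 1e-8)
})

test_that("under the null no CpG reaches genome-wide significance in >= 99% of seeds", {
  hits <- vapply(1:100, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 300, n_cpgs = 50,
                                      seed = s))
    ew <- fit_ewas(sim$bundle, covariate_columns = c("sex", "bmi"))
    sum(ew$pval < 1e-7)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(exposure_prevalence = 1.2),
               "exposure_prevalence")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(paternal_shared_env_corr = 2),
               "paternal_shared_env_corr")
  expect_error(sim_config(n_cpgs = 5, effect_sizes = c(cpg_9 = 0.1)),
               "cpg_9")
  expect_error(sim_config(effect_sizes = c(cpg_1 = NaN)), "effect_sizes")
})

test_that("second timepoint scales the exposure effect by the persistence fraction", {
  cfg1 <- noiseless_config(n_samples = 60, n_cpgs = 2,
                           effect_sizes = c(cpg_1 = 0.04),
                           persistence_fractions = c(cpg_1 = 1),
                           noise_sd_t2 = 0)
  s1 <- simulate_cohort(cfg1)
  b2 <- simulate_second_timepoint(s1$bundle, cfg1)
  expect_identical(b2$covariates$sample_id, s1$bundle$covariates$sample_id)
  expect_equal(b2$methylation, s1$bundle$methylation, tolerance = 1e-12)

  cfg0 <- noiseless_config(n_samples = 60, n_cpgs = 2,
                           effect_sizes = c(cpg_1 = 0.04),
                           persistence_fractions = c(cpg_1 = 0),
                           noise_sd_t2 = 0)
  s0 <- simulate_cohort(cfg0)
  b0 <- simulate_second_timepoint(s0$bundle, cfg0)
  expo <- s0$bundle$covariates$maternal_smoking
  d2 <- mean(b0$methylation[expo == 1, "cpg_1"]) -
    mean(b0$methylation[expo == 0, "cpg_1"])
  expect_equal(d2, 0, tolerance = 1e-12)
  # altered sample set rejected
  broken <- s0$bundle
  broken$covariates <- broken$covariates[-1, ]
  expect_error(simulate_second_timepoint(broken, cfg0), "sample")
})

test_that("MR inputs satisfy the product identity and LD contracts", {
  cfg <- sim_config(n_cpgs = 2, n_snps = 1,
                    mqtl_effects = data.frame(snp = "rs1", cpg = "cpg_1",
                                              beta = 0.2),
                    causal_cpg_effects_on_outcome = c(cpg_1 = -0.5),
                    mqtl_sample_size = Inf, gwas_sample_size = Inf,
                    seed = 3)
  inp <- simulate_mr_inputs(cfg)
  expect_equal(inp$mqtl$beta, 0.2, tolerance = 1e-15)
  expect_equal(inp$gwas$beta, -0.10, tolerance = 1e-15)
  expect_equal(unname(diag(inp$ld)), 1)
  # PSD with AR(1) LD
  cfg2 <- sim_config(n_cpgs = 2, n_snps = 6,
                     mqtl_effects = data.frame(snp = "rs1", cpg = "cpg_1",
                                               beta = 0.2),
                     ld_rho = 0.6, seed = 3)
  ld <- simulate_mr_inputs(cfg2)$ld
  expect_identical(ld, t(ld))
  expect_gte(min(eigen(ld, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # a zero mQTL effect is an unusable instrument
  expect_error(
    sim_config(n_cpgs = 2, n_snps = 1,
               mqtl_effects = data.frame(snp = "rs1", cpg = "cpg_1",
                                         beta = 0)),
    "zero effect"
  )
})

test_that("Wald estimates from simulated null instruments center on zero", {
  est <- vapply(1:200, function(s) {
    cfg <- sim_config(n_cpgs = 1, n_snps = 1,
                      mqtl_effects = data.frame(snp = "rs1", cpg = "cpg_1",
                                                beta = 0.2),
                      causal_cpg_effects_on_outcome = c(cpg_1 = 0),
                      mqtl_sample_size = 5000, gwas_sample_size = 20000,
                      seed = s)
    inp <- simulate_mr_inputs(cfg)
    wald_ratio(inp$mqtl$beta, inp$mqtl$se, inp$gwas$beta,
               inp$gwas$se)$beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 3 * mc_se)
})

test_that("every downstream estimand has a truth-record counterpart", {
  cfg <- sim_config(n_samples = 50, n_cpgs = 4,
                    effect_sizes = c(cpg_1 = 0.05),
                    dose_slopes = c(cpg_2 = 0.01),
                    persistence_fractions = c(cpg_1 = 0.5),
                    causal_cpg_effects_on_outcome = c(cpg_1 = 1),
                    direct_exposure_effect_on_outcome = 0.2,
                    seed = 2)
  truth <- simulate_cohort(cfg)$truth
  expect_setequal(names(truth$cpg),
                  c("cpg_id", "effect", "dose_slope",
                    "persistence_fraction"))
  expect_equal(nrow(truth$cpg), 4)
  med <- truth$mediation
  expect_equal(med$total_effect, med$acme + med$ade, tolerance = 1e-12)
  expect_equal(med$prop_mediated, med$acme / med$total_effect,
               tolerance = 1e-12)
})
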