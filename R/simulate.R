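#' Simulation configuration for synthetic birth-cohort data
#'
#' Collects every knob of the generative model used to emulate a birth
#' cohort with prenatal smoking exposure, blood DNA methylation measured
#' on the beta-value scale, and the genetic / summary-statistic inputs of
#' the downstream Mendelian randomization and mediation stages. Defaults
#' describe a cohort of the size and noise level at which published
#' exposure effects of 0.005-0.08 beta units are detectable once several
#' cohorts are meta-analyzed (roughly 2800 samples in total).
#'
#' Methylation is simulated directly on the beta-value scale as
#' baseline + exposure effect + dose slope x cigarettes/day + covariate
#' loadings + cell-type mixture contribution + Gaussian noise, then
#' clipped to \[0, 1\]. Cigarettes/day for exposed mothers follow a
#' zero-truncated Poisson with the configured mean ("at least one
#' cigarette per day"); unexposed mothers are fixed at 0. Maternal and
#' paternal smoking share a latent environment (bivariate normal
#' liability with the configured correlation); paternal smoking has no
#' direct effect on methylation, which is the negative-control
#' assumption. Cell-type proportions are Dirichlet distributed with
#' CpG-specific loadings.
#'
#' @param n_samples Samples per cohort.
#' @param n_cpgs Number of CpG sites.
#' @param n_chromosomes Chromosomes over which CpGs/SNPs are scattered.
#' @param exposure_prevalence Probability of prenatal smoking exposure
#'   (maternal smoking), strictly inside (0, 1).
#' @param mean_cigs_per_day_given_exposed Mean cigarettes/day among
#'   exposed mothers (mean of the zero-truncated Poisson).
#' @param paternal_prevalence Marginal probability of paternal smoking.
#' @param paternal_shared_env_corr Latent (liability-scale) correlation
#'   between maternal and paternal smoking, in \[-1, 1\].
#' @param effect_sizes Named numeric vector, CpG id -> exposure effect in
#'   beta-value units (difference exposed minus unexposed).
#' @param dose_slopes Named numeric vector, CpG id -> beta-value change
#'   per additional cigarette/day.
#' @param persistence_fractions Named numeric vector, CpG id -> fraction
#'   of the timepoint-1 exposure effect retained at timepoint 2 (in
#'   \[0, 1\]).
#' @param noise_sd Residual SD of methylation in beta-value units.
#' @param noise_sd_t2 Residual SD at the second timepoint (defaults to
#'   `1.2 * noise_sd`, i.e. mildly heteroskedastic between timepoints).
#' @param timepoint_residual_corr Within-individual correlation of
#'   methylation residuals across the two timepoints.
#' @param covariate_loading_sd SD of per-CpG loadings on standardized
#'   non-exposure covariates (sex, BMI, age, PCs).
#' @param cell_loading_sd SD of per-CpG loadings on centered cell-type
#'   proportions.
#' @param cell_type_count Number of leukocyte subtypes.
#' @param n_genetic_pcs,n_technical_pcs Numbers of genetic and technical
#'   principal components emitted as covariates.
#' @param n_snps Number of SNPs for the Mendelian randomization inputs.
#' @param mqtl_effects Tibble/data frame with columns `snp`, `cpg`,
#'   `beta`: true per-allele SNP -> CpG methylation effects.
#' @param causal_cpg_effects_on_outcome Named numeric vector, CpG id ->
#'   true effect of methylation on the outcome (outcome units per
#'   beta-value unit).
#' @param direct_exposure_effect_on_outcome True direct (non-mediated)
#'   exposure effect on the outcome.
#' @param outcome_model `"linear"` for a continuous trait
#'   (personality-scale analogue) or `"logistic"` for a binary disease
#'   generated by a liability-threshold model.
#' @param outcome_noise_sd Residual SD of the continuous outcome (and of
#'   the liability for binary outcomes).
#' @param disease_prevalence Marginal prevalence for binary outcomes.
#' @param own_smoking_prevalence Prevalence of offspring's own regular
#'   smoking (independent of exposure by default, so never-smoker
#'   subsetting is a pure sensitivity analysis).
#' @param mqtl_sample_size,gwas_sample_size Effective sample sizes that
#'   set the sampling error of the emitted mQTL and GWAS summary
#'   statistics.
#' @param ld_rho AR(1) correlation between consecutive SNPs on a
#'   chromosome in the emitted LD matrix (0 gives independent SNPs).
#' @param seed Integer seed; all outputs are deterministic given it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 560,
                       n_cpgs = 100,
                       n_chromosomes = 22,
                       exposure_prevalence = 0.16,
                       mean_cigs_per_day_given_exposed = 3,
                       paternal_prevalence = 0.30,
                       paternal_shared_env_corr = 0.5,
                       effect_sizes = numeric(),
                       dose_slopes = numeric(),
                       persistence_fractions = numeric(),
                       noise_sd = 0.05,
                       noise_sd_t2 = NULL,
                       timepoint_residual_corr = 0.4,
                       covariate_loading_sd = 0.002,
                       cell_loading_sd = 0.02,
                       cell_type_count = 6,
                       n_genetic_pcs = 4,
                       n_technical_pcs = 10,
                       n_snps = 0,
                       mqtl_effects = NULL,
                       causal_cpg_effects_on_outcome = numeric(),
                       direct_exposure_effect_on_outcome = 0,
                       outcome_model = c("linear", "logistic"),
                       outcome_noise_sd = 1,
                       disease_prevalence = 0.1,
                       own_smoking_prevalence = 0.25,
                       mqtl_sample_size = 1000,
                       gwas_sample_size = 20000,
                       ld_rho = 0,
                       seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_cpgs <- assert_count(n_cpgs, "n_cpgs")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  assert_scalar_number(exposure_prevalence, "exposure_prevalence",
                       0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(mean_cigs_per_day_given_exposed,
                       "mean_cigs_per_day_given_exposed", 1, Inf)
  assert_scalar_number(paternal_prevalence, "paternal_prevalence",
                       0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(paternal_shared_env_corr,
                       "paternal_shared_env_corr", -1, 1)
  assert_scalar_number(noise_sd, "noise_sd", 0, Inf)
  if (is.null(noise_sd_t2)) noise_sd_t2 <- 1.2 * noise_sd
  assert_scalar_number(noise_sd_t2, "noise_sd_t2", 0, Inf)
  assert_scalar_number(timepoint_residual_corr, "timepoint_residual_corr",
                       -1, 1)
  assert_scalar_number(covariate_loading_sd, "covariate_loading_sd", 0, Inf)
  assert_scalar_number(cell_loading_sd, "cell_loading_sd", 0, Inf)
  cell_type_count <- assert_count(cell_type_count, "cell_type_count", 2L)
  n_genetic_pcs <- assert_count(n_genetic_pcs, "n_genetic_pcs", 0L)
  n_technical_pcs <- assert_count(n_technical_pcs, "n_technical_pcs", 0L)
  n_snps <- assert_count(n_snps, "n_snps", 0L)
  assert_scalar_number(direct_exposure_effect_on_outcome,
                       "direct_exposure_effect_on_outcome")
  outcome_model <- match.arg(outcome_model)
  assert_scalar_number(outcome_noise_sd, "outcome_noise_sd", 0, Inf)
  assert_scalar_number(disease_prevalence, "disease_prevalence",
                       0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(own_smoking_prevalence, "own_smoking_prevalence",
                       0, 1, strict_lower = TRUE, strict_upper = TRUE)
  # Inf is allowed and means summary statistics without sampling error
  if (!(length(mqtl_sample_size) == 1L && is.numeric(mqtl_sample_size) &&
        (is.infinite(mqtl_sample_size) || mqtl_sample_size >= 1))) {
    abort("`mqtl_sample_size` must be a positive count or Inf.")
  }
  if (!(length(gwas_sample_size) == 1L && is.numeric(gwas_sample_size) &&
        (is.infinite(gwas_sample_size) || gwas_sample_size >= 1))) {
    abort("`gwas_sample_size` must be a positive count or Inf.")
  }
  assert_scalar_number(ld_rho, "ld_rho", -1, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  seed <- assert_count(seed, "seed", minimum = 0L)

  cpg_ids <- paste0("cpg_", seq_len(n_cpgs))
  check_map <- function(map, field, lower = -Inf, upper = Inf) {
    if (length(map) == 0L) return(setNames(numeric(), character()))
    if (!is.numeric(map) || is.null(names(map)) || any(names(map) == "")) {
      abort(sprintf("`%s` must be a named numeric vector (CpG id -> value).",
                    field))
    }
    if (any(!is.finite(map))) {
      abort(sprintf("`%s` contains non-finite values.", field))
    }
    bad <- setdiff(names(map), cpg_ids)
    if (length(bad) > 0L) {
      abort(sprintf("`%s` maps unknown CpG id%s: %s (ids run cpg_1..cpg_%d).",
                    field, if (length(bad) > 1L) "s" else "",
                    paste(head(bad, 5L), collapse = ", "), n_cpgs))
    }
    if (any(map < lower | map > upper)) {
      abort(sprintf("`%s` values must lie in [%g, %g].", field, lower, upper))
    }
    map
  }
  effect_sizes <- check_map(effect_sizes, "effect_sizes")
  dose_slopes <- check_map(dose_slopes, "dose_slopes")
  persistence_fractions <- check_map(persistence_fractions,
                                     "persistence_fractions", 0, 1)
  causal_cpg_effects_on_outcome <-
    check_map(causal_cpg_effects_on_outcome, "causal_cpg_effects_on_outcome")

  if (!is.null(mqtl_effects)) {
    mqtl_effects <- tibble::as_tibble(mqtl_effects)
    assert_columns(mqtl_effects, c("snp", "cpg", "beta"), "`mqtl_effects`")
    if (any(!is.finite(mqtl_effects$beta))) {
      abort("`mqtl_effects` contains non-finite betas.")
    }
    if (any(mqtl_effects$beta == 0)) {
      abort(paste0("`mqtl_effects` assigns a zero effect to an instrument ",
                   "SNP; a null instrument is unusable."))
    }
    bad <- setdiff(mqtl_effects$cpg, cpg_ids)
    if (length(bad) > 0L) {
      abort(sprintf("`mqtl_effects` maps unknown CpG id%s: %s.",
                    if (length(bad) > 1L) "s" else "",
                    paste(head(bad, 5L), collapse = ", ")))
    }
  }

  structure(
    list(
      n_samples = n_samples, n_cpgs = n_cpgs, n_chromosomes = n_chromosomes,
      exposure_prevalence = exposure_prevalence,
      mean_cigs_per_day_given_exposed = mean_cigs_per_day_given_exposed,
      paternal_prevalence = paternal_prevalence,
      paternal_shared_env_corr = paternal_shared_env_corr,
      effect_sizes = effect_sizes, dose_slopes = dose_slopes,
      persistence_fractions = persistence_fractions,
      noise_sd = noise_sd, noise_sd_t2 = noise_sd_t2,
      timepoint_residual_corr = timepoint_residual_corr,
      covariate_loading_sd = covariate_loading_sd,
      cell_loading_sd = cell_loading_sd,
      cell_type_count = cell_type_count,
      n_genetic_pcs = n_genetic_pcs, n_technical_pcs = n_technical_pcs,
      n_snps = n_snps, mqtl_effects = mqtl_effects,
      causal_cpg_effects_on_outcome = causal_cpg_effects_on_outcome,
      direct_exposure_effect_on_outcome = direct_exposure_effect_on_outcome,
      outcome_model = outcome_model, outcome_noise_sd = outcome_noise_sd,
      disease_prevalence = disease_prevalence,
      own_smoking_prevalence = own_smoking_prevalence,
      mqtl_sample_size = mqtl_sample_size,
      gwas_sample_size = gwas_sample_size,
      ld_rho = ld_rho, seed = seed,
      cpg_ids = cpg_ids
    ),
    class = "sim_config"
  )
}

# Poisson rate whose zero-truncated mean equals `target_mean`.
ztpois_lambda <- function(target_mean) {
  if (target_mean <= 1) return(1e-8)  # degenerate: almost surely 1
  f <- function(l) l / (1 - exp(-l)) - target_mean
  stats::uniroot(f, c(1e-8, target_mean), tol = 1e-12)$root
}

rztpois <- function(n, lambda) {
  # inversion restricted to k >= 1
  p0 <- ppois(0, lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

expand_map <- function(map, cpg_ids) {
  v <- setNames(numeric(length(cpg_ids)), cpg_ids)
  v[names(map)] <- map
  v
}

#' Simulate one birth cohort with known ground truth
#'
#' Generates a methylation matrix, CpG annotation, and sample covariate
#' table with the statistical structure the downstream stages assume:
#' exposure effects with optional dose dependence, covariate and
#' cell-type loadings, Gaussian noise clipped to \[0, 1\], a paternal
#' smoking indicator correlated with maternal smoking through a shared
#' environment but with zero direct effect on methylation, and (when
#' configured) an outcome with a known mediated fraction through CpGs.
#'
#' @param config A [sim_config()].
#' @param timepoint Label for the timepoint (default `"t1"`).
#' @return A list with elements `bundle` (class `cohort_bundle`: list of
#'   `methylation` samples x CpGs matrix, `annotation` tibble,
#'   `covariates` tibble, `timepoint`) and `truth` (class
#'   `truth_record`), the realized per-CpG true effects and true
#'   mediation quantities used by recovery tests.
#' @export
simulate_cohort <- function(config, timepoint = "t1") {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  with_seed(config$seed, simulate_cohort_impl(config, timepoint))
}

simulate_cohort_impl <- function(config, timepoint) {
  n <- config$n_samples
  m <- config$n_cpgs
  cpg_ids <- config$cpg_ids
  sample_ids <- sprintf("s%04d", seq_len(n))

  # annotation: CpGs scattered over chromosomes, 1-based positions
  chrom <- sort(sample.int(config$n_chromosomes, m, replace = TRUE))
  position <- sample.int(2e8L, m, replace = TRUE)
  annotation <- tibble::tibble(
    cpg_id = cpg_ids,
    chromosome = as.character(chrom),
    position = as.integer(position),
    gene = paste0("GENE", chrom)
  )

  # exposure pair via shared-environment (bivariate normal liability)
  rho <- config$paternal_shared_env_corr
  shared <- rnorm(n)
  liab_m <- sqrt(abs(rho)) * shared * sign(rho) + sqrt(1 - abs(rho)) * rnorm(n)
  liab_p <- sqrt(abs(rho)) * shared + sqrt(1 - abs(rho)) * rnorm(n)
  maternal <- as.integer(liab_m > qnorm(1 - config$exposure_prevalence))
  paternal <- as.integer(liab_p > qnorm(1 - config$paternal_prevalence))

  cigs <- numeric(n)
  n_exp <- sum(maternal)
  if (n_exp > 0L) {
    lambda <- ztpois_lambda(config$mean_cigs_per_day_given_exposed)
    cigs[maternal == 1L] <- rztpois(n_exp, lambda)
  }

  own_smoking <- rbinom(n, 1L, config$own_smoking_prevalence)
  sex <- rbinom(n, 1L, 0.5)
  bmi <- rnorm(n, 25, 4)
  age <- rnorm(n, 31, 1.5)
  social_class <- sample.int(5L, n, replace = TRUE)
  gpc <- if (config$n_genetic_pcs > 0)
    matrix(rnorm(n * config$n_genetic_pcs), n) else NULL
  tpc <- if (config$n_technical_pcs > 0)
    matrix(rnorm(n * config$n_technical_pcs), n) else NULL

  # blood cell mixture; neutrophil-dominant when six subtypes
  alpha <- if (config$cell_type_count == 6L) {
    c(27, 8, 5, 3, 3, 4)
  } else {
    rep(5, config$cell_type_count)
  }
  cellp <- rdirichlet_rows(n, alpha)

  effects <- expand_map(config$effect_sizes, cpg_ids)
  doses <- expand_map(config$dose_slopes, cpg_ids)

  baseline <- runif(m, 0.2, 0.8)
  covmat <- cbind(
    sex = sex, bmi = scale(bmi)[, 1], age = scale(age)[, 1],
    gpc, tpc
  )
  load_cov <- matrix(
    rnorm(ncol(covmat) * m, 0, config$covariate_loading_sd),
    nrow = ncol(covmat)
  )
  cell_centered <- sweep(cellp, 2, colMeans(cellp))
  load_cell <- matrix(
    rnorm(config$cell_type_count * m, 0, config$cell_loading_sd),
    nrow = config$cell_type_count
  )
  noise_std <- matrix(rnorm(n * m), n, m)

  signal <- matrix(baseline, n, m, byrow = TRUE) +
    maternal %o% effects +
    cigs %o% doses +
    covmat %*% load_cov +
    cell_centered %*% load_cell
  meth <- signal + config$noise_sd * noise_std
  clipped <- meth < 0 | meth > 1
  if (any(clipped)) {
    frac <- mean(clipped)
    inform(sprintf("clipped %d methylation values (%.4f%%) to [0, 1].",
                   sum(clipped), 100 * frac))
    meth[meth < 0] <- 0
    meth[meth > 1] <- 1
  }
  dimnames(meth) <- list(sample_ids, cpg_ids)

  covariates <- tibble::tibble(
    sample_id = sample_ids,
    maternal_smoking = maternal,
    cigs_per_day = cigs,
    paternal_smoking = paternal,
    own_smoking = own_smoking,
    sex = sex,
    bmi = bmi,
    social_class = social_class,
    age = age
  )
  if (!is.null(gpc)) {
    colnames(gpc) <- paste0("gpc_", seq_len(ncol(gpc)))
    covariates <- dplyr::bind_cols(covariates, tibble::as_tibble(gpc))
  }
  if (!is.null(tpc)) {
    colnames(tpc) <- paste0("tpc_", seq_len(ncol(tpc)))
    covariates <- dplyr::bind_cols(covariates, tibble::as_tibble(tpc))
  }
  colnames(cellp) <- paste0("cell_prop_", seq_len(ncol(cellp)))
  covariates <- dplyr::bind_cols(covariates, tibble::as_tibble(cellp))

  # outcome with known mediated fraction through the causal CpGs
  truth_mediation <- NULL
  lam <- ztpois_lambda(config$mean_cigs_per_day_given_exposed)
  mean_cigs_exposed <- lam / (1 - exp(-lam))
  if (length(config$causal_cpg_effects_on_outcome) > 0L ||
      config$direct_exposure_effect_on_outcome != 0) {
    bvec <- expand_map(config$causal_cpg_effects_on_outcome, cpg_ids)
    lin <- config$direct_exposure_effect_on_outcome * maternal +
      drop(meth %*% bvec)
    if (config$outcome_model == "linear") {
      outcome <- lin + rnorm(n, 0, config$outcome_noise_sd)
    } else {
      liab <- lin + rnorm(n, 0, config$outcome_noise_sd)
      thr <- quantile(liab, 1 - config$disease_prevalence, names = FALSE)
      outcome <- as.integer(liab > thr)
    }
    covariates$outcome <- outcome
    # true paths: exposure shifts mediator by effect + dose * E[cigs|exposed]
    a_true <- effects + doses * mean_cigs_exposed
    acme <- sum(bvec * a_true)
    ade <- config$direct_exposure_effect_on_outcome
    truth_mediation <- list(
      acme = acme, ade = ade, total_effect = acme + ade,
      prop_mediated = if ((acme + ade) != 0) acme / (acme + ade) else NA_real_
    )
  }

  bundle <- structure(
    list(
      methylation = meth,
      annotation = annotation,
      covariates = covariates,
      timepoint = timepoint,
      internals = list(
        baseline = baseline, covmat = covmat, load_cov = load_cov,
        cell_centered = cell_centered, load_cell = load_cell,
        noise_std = noise_std, effects = effects, doses = doses,
        maternal = maternal, cigs = cigs, sample_ids = sample_ids
      )
    ),
    class = "cohort_bundle"
  )
  truth <- structure(
    list(
      cpg = tibble::tibble(
        cpg_id = cpg_ids,
        effect = unname(effects),
        dose_slope = unname(doses),
        persistence_fraction =
          unname(expand_map(config$persistence_fractions, cpg_ids))
      ),
      mean_cigs_exposed = mean_cigs_exposed,
      mediation = truth_mediation,
      seed = config$seed
    ),
    class = "truth_record"
  )
  list(bundle = bundle, truth = truth)
}

#' Construct a cohort bundle from raw tables
#'
#' Assembles and validates the per-cohort container used throughout the
#' pipeline: a samples x CpGs beta-value matrix, a CpG annotation table,
#' and a sample covariate table.
#'
#' @param methylation Numeric matrix of beta values, samples in rows
#'   (row names are sample ids), CpGs in columns (column names are CpG
#'   ids).
#' @param annotation Tibble with columns `cpg_id`, `chromosome`,
#'   `position` (1-based), `gene`.
#' @param covariates Tibble with a `sample_id` column matching the
#'   matrix rows plus covariate columns.
#' @param timepoint Timepoint label.
#' @return A `cohort_bundle`.
#' @export
cohort_bundle <- function(methylation, annotation, covariates,
                          timepoint = "t1") {
  if (!is.matrix(methylation) || !is.numeric(methylation)) {
    abort("`methylation` must be a numeric matrix (samples x CpGs).")
  }
  covariates <- tibble::as_tibble(covariates)
  assert_columns(covariates, "sample_id", "covariate table")
  assert_no_duplicates(covariates$sample_id, "sample_id")
  if (is.null(rownames(methylation)) ||
      !setequal(rownames(methylation), covariates$sample_id)) {
    abort("sample sets of methylation matrix and covariate table differ.")
  }
  methylation <- methylation[covariates$sample_id, , drop = FALSE]
  if (any(methylation < 0 | methylation > 1)) {
    abort("methylation beta values must lie in [0, 1].")
  }
  annotation <- tibble::as_tibble(annotation)
  assert_columns(annotation, c("cpg_id", "chromosome", "position", "gene"),
                 "annotation table")
  if (any(annotation$position <= 0 |
          annotation$position != round(annotation$position))) {
    abort("annotation positions must be strictly positive integers.")
  }
  cellcols <- grep("^cell_prop_", names(covariates), value = TRUE)
  if (length(cellcols) > 0L) {
    sums <- rowSums(covariates[, cellcols, drop = FALSE])
    if (any(abs(sums - 1) > 1e-8) || any(covariates[, cellcols] < 0)) {
      abort("cell proportions must be nonnegative and sum to 1 (tol 1e-8).")
    }
  }
  structure(
    list(methylation = methylation, annotation = annotation,
         covariates = covariates, timepoint = timepoint, internals = NULL),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d samples x %d CpGs, timepoint '%s'\n",
    nrow(x$methylation), ncol(x$methylation), x$timepoint
  ))
  invisible(x)
}

#' Simulate a second methylation timepoint for an existing cohort
#'
#' The same individuals are measured again: the exposure effect at
#' timepoint 2 equals `persistence_fraction` times the timepoint-1
#' effect (per CpG; CpGs absent from the map retain their effect fully),
#' residuals are correlated within individual across timepoints at
#' `timepoint_residual_corr`, and the residual SD may differ between
#' timepoints (`noise_sd_t2`).
#'
#' @param bundle A timepoint-1 `cohort_bundle` from [simulate_cohort()].
#' @param config The same [sim_config()] used to generate `bundle`.
#' @param timepoint Label for the new timepoint (default `"t2"`).
#' @param age_gap Years added to the age covariate (default 15).
#' @return A `cohort_bundle` for timepoint 2 with identical samples.
#' @export
simulate_second_timepoint <- function(bundle, config, timepoint = "t2",
                                      age_gap = 15) {
  if (!inherits(bundle, "cohort_bundle") || is.null(bundle$internals)) {
    abort("`bundle` must be a timepoint-1 cohort from simulate_cohort().")
  }
  if (!identical(bundle$covariates$sample_id, bundle$internals$sample_ids)) {
    abort("sample sets of `bundle` have been altered; cannot extend.")
  }
  with_seed(config$seed + 1L, {
    int <- bundle$internals
    n <- nrow(bundle$methylation)
    m <- ncol(bundle$methylation)
    persist <- expand_map(config$persistence_fractions, config$cpg_ids)
    persist[setdiff(config$cpg_ids, names(config$persistence_fractions))] <- 1
    rho <- config$timepoint_residual_corr
    noise2_std <- rho * int$noise_std + sqrt(1 - rho^2) * matrix(rnorm(n * m), n, m)
    meth2 <- matrix(int$baseline, n, m, byrow = TRUE) +
      int$maternal %o% (int$effects * persist) +
      int$cigs %o% (int$doses * persist) +
      int$covmat %*% int$load_cov +
      int$cell_centered %*% int$load_cell +
      config$noise_sd_t2 * noise2_std
    meth2[meth2 < 0] <- 0
    meth2[meth2 > 1] <- 1
    dimnames(meth2) <- dimnames(bundle$methylation)
    cov2 <- bundle$covariates
    cov2$age <- cov2$age + age_gap
    structure(
      list(
        methylation = meth2,
        annotation = bundle$annotation,
        covariates = cov2,
        timepoint = timepoint,
        internals = NULL
      ),
      class = "cohort_bundle"
    )
  })
}

#' Simulate two-sample Mendelian randomization inputs
#'
#' Emits mQTL (SNP -> CpG) and GWAS (SNP -> outcome) summary-statistic
#' tables plus an LD correlation matrix, under a valid-instrument model:
#' the SNP -> outcome effect equals the true causal effect of the CpG on
#' the outcome times the SNP -> CpG effect, with sampling error scaled
#' by the configured instrument and GWAS sample sizes; direct
#' (pleiotropic) SNP -> outcome paths are zero.
#'
#' @param config A [sim_config()] with `n_snps >= 1` and a non-empty
#'   `mqtl_effects` table.
#' @param trait_effects Optional tibble with columns `trait_id`,
#'   `cpg_id`, `theta` giving the true causal effect of each CpG on each
#'   trait. Defaults to a single trait `"trait_1"` whose per-CpG effects
#'   come from `config$causal_cpg_effects_on_outcome` (zero for
#'   unmapped CpGs).
#' @return A list: `mqtl` (tibble: snp, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, cpg), `gwas` (tibble: snp,
#'   effect_allele, other_allele, eaf, beta, se, pval, trait_id), `ld`
#'   (named correlation matrix, unit diagonal), and `truth` (tibble:
#'   trait_id, cpg_id, theta).
#' @export
simulate_mr_inputs <- function(config, trait_effects = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  if (config$n_snps < 1L) abort("`n_snps` must be >= 1 for MR inputs.")
  if (is.null(config$mqtl_effects)) {
    abort("`mqtl_effects` must be supplied in the config for MR inputs.")
  }
  with_seed(config$seed + 2L, {
    snp_ids <- paste0("rs", seq_len(config$n_snps))
    bad <- setdiff(config$mqtl_effects$snp, snp_ids)
    if (length(bad) > 0L) {
      abort(sprintf("`mqtl_effects` names unknown SNP%s: %s.",
                    if (length(bad) > 1L) "s" else "",
                    paste(head(bad, 5L), collapse = ", ")))
    }
    chr <- sort(sample.int(config$n_chromosomes, config$n_snps,
                           replace = TRUE))
    pos <- sample.int(2e8L, config$n_snps)
    eaf <- runif(config$n_snps, 0.1, 0.9)
    # non-palindromic allele pairs so harmonization never drops instruments
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- pairs[sample.int(nrow(pairs), config$n_snps, replace = TRUE), ,
                  drop = FALSE]
    snp_tbl <- tibble::tibble(
      snp = snp_ids, chr = as.character(chr), pos = as.integer(pos),
      effect_allele = pick[, 1], other_allele = pick[, 2], eaf = eaf
    )

    if (is.null(trait_effects)) {
      theta <- expand_map(config$causal_cpg_effects_on_outcome,
                          config$cpg_ids)
      trait_effects <- tibble::tibble(
        trait_id = "trait_1",
        cpg_id = config$cpg_ids,
        theta = unname(theta)
      )
    } else {
      trait_effects <- tibble::as_tibble(trait_effects)
      assert_columns(trait_effects, c("trait_id", "cpg_id", "theta"),
                     "`trait_effects`")
    }

    mq <- dplyr::left_join(
      tibble::as_tibble(config$mqtl_effects), snp_tbl, by = "snp"
    )
    se_mq <- 1 / sqrt(2 * mq$eaf * (1 - mq$eaf) * config$mqtl_sample_size)
    se_mq <- se_mq * pmax(config$noise_sd, 0.01)  # per-allele effect on beta scale
    mq_beta <- mq$beta + rnorm(nrow(mq), 0, se_mq)
    mqtl <- tibble::tibble(
      snp = mq$snp, chr = mq$chr, pos = mq$pos,
      effect_allele = mq$effect_allele, other_allele = mq$other_allele,
      eaf = mq$eaf, beta = mq_beta, se = se_mq,
      pval = two_sided_normal_p(mq_beta / se_mq),
      cpg = mq$cpg
    )

    # GWAS: per trait, SNP effect = sum over CpGs of theta * true SNP->CpG
    true_snp_cpg <- tibble::as_tibble(config$mqtl_effects)
    gwas <- purrr::map_dfr(unique(trait_effects$trait_id), function(tr) {
      th <- trait_effects[trait_effects$trait_id == tr, ]
      eff <- dplyr::left_join(true_snp_cpg,
                              th[, c("cpg_id", "theta")],
                              by = c("cpg" = "cpg_id"))
      eff$theta[is.na(eff$theta)] <- 0
      per_snp <- tapply(eff$beta * eff$theta, eff$snp, sum)
      b_true <- setNames(numeric(config$n_snps), snp_ids)
      b_true[names(per_snp)] <- per_snp
      se_g <- 1 / sqrt(2 * snp_tbl$eaf * (1 - snp_tbl$eaf) *
                         config$gwas_sample_size)
      b_obs <- unname(b_true) + rnorm(config$n_snps, 0, se_g)
      tibble::tibble(
        snp = snp_ids,
        effect_allele = snp_tbl$effect_allele,
        other_allele = snp_tbl$other_allele,
        eaf = snp_tbl$eaf,
        beta = b_obs, se = se_g,
        pval = two_sided_normal_p(b_obs / se_g),
        trait_id = tr
      )
    })

    # AR(1) LD within chromosome, zero across
    ld <- diag(config$n_snps)
    if (config$ld_rho != 0 && config$n_snps > 1L) {
      ord <- order(chr, pos)
      for (i in seq_len(config$n_snps - 1L)) {
        for (j in (i + 1L):config$n_snps) {
          if (chr[ord[i]] == chr[ord[j]]) {
            r <- config$ld_rho^(j - i)
            ld[ord[i], ord[j]] <- r
            ld[ord[j], ord[i]] <- r
          }
        }
      }
    }
    dimnames(ld) <- list(snp_ids, snp_ids)

    list(mqtl = mqtl, gwas = gwas, ld = ld, truth = trait_effects)
  })
}
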