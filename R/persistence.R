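#' Residualize methylation on technical and cell-type covariates
#'
#' Per CpG, regresses methylation on the supplied covariates by ordinary
#' least squares and returns the residuals (first stage of the
#' two-stage longitudinal procedure). With no covariates the result is
#' the column-centered matrix. Residual columns have mean zero and are
#' orthogonal to every covariate column.
#'
#' @param methylation Samples x CpGs numeric matrix with sample ids as
#'   row names.
#' @param covariates A tibble/data frame of covariates (one row per
#'   sample, same order as the matrix rows), or `NULL` for centering
#'   only. A `sample_id` column, if present, is used to check alignment
#'   and then dropped.
#' @return A residual matrix with the same dimensions and dimnames.
#' @export
residualize <- function(methylation, covariates = NULL) {
  if (!is.matrix(methylation) || !is.numeric(methylation)) {
    abort("`methylation` must be a numeric matrix (samples x CpGs).")
  }
  n <- nrow(methylation)
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if ("sample_id" %in% names(covariates)) {
      if (!is.null(rownames(methylation)) &&
          !identical(covariates$sample_id, rownames(methylation))) {
        abort("covariate rows are not aligned with methylation rows.")
      }
      covariates$sample_id <- NULL
    }
    if (nrow(covariates) != n) {
      abort("covariate table and methylation matrix differ in rows.")
    }
  }
  if (is.null(covariates) || ncol(covariates) == 0L) {
    return(scale(methylation, center = TRUE, scale = FALSE))
  }
  X <- model.matrix(~., data = as.data.frame(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(sprintf("covariate design is rank deficient (column%s %s).",
                  if (length(bad) > 1L) "s" else "",
                  paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qx, methylation)
  dimnames(res) <- dimnames(methylation)
  res
}

#' Two-timepoint GLS persistence model
#'
#' For each CpG, fits a stacked model of residualized methylation at two
#' timepoints on exposure, timepoint, their interaction, and study
#' covariates, by iterated feasible generalized least squares with an
#' unstructured 2x2 within-individual error covariance (one variance per
#' timepoint, one cross-timepoint correlation). The per-timepoint
#' exposure effects are derived from the coefficients, and the test for
#' equality of the two effects is the test of the interaction term being
#' zero. Individuals present at only one timepoint are retained
#' (unbalanced GLS).
#'
#' @param res_t1,res_t2 Residual matrices (samples x CpGs) from
#'   [residualize()], with sample ids as row names; the CpG sets must
#'   match. Sample sets may differ (unbalanced follow-up).
#' @param exposure Named 0/1 vector of time-invariant exposure, names
#'   covering every sample id in either matrix.
#' @param covariates_t1,covariates_t2 Optional tibbles of study
#'   covariates per timepoint (rows aligned with the respective residual
#'   matrix; a `sample_id` column is used for the alignment check and
#'   dropped). Columns must match between timepoints.
#' @param max_iter Iteration cap for the feasible GLS (default 100).
#' @param tol Relative coefficient-change tolerance for convergence
#'   (default 1e-8).
#' @return A tibble with one row per CpG: `cpg_id`, `beta_t1`, `se_t1`,
#'   `beta_t2`, `se_t2`, `interaction_beta`, `interaction_se`,
#'   `equality_pval`, `resid_sd_t1`, `resid_sd_t2`, `resid_corr`,
#'   `converged`, `n_individuals`, `n_paired`.
#' @export
fit_gls_persistence <- function(res_t1, res_t2, exposure,
                                covariates_t1 = NULL, covariates_t2 = NULL,
                                max_iter = 100, tol = 1e-8) {
  if (!identical(colnames(res_t1), colnames(res_t2))) {
    abort("CpG sets of the two timepoints differ.")
  }
  ids1 <- rownames(res_t1)
  ids2 <- rownames(res_t2)
  if (is.null(ids1) || is.null(ids2)) {
    abort("residual matrices must carry sample ids as row names.")
  }
  all_ids <- union(ids1, ids2)
  if (is.null(names(exposure)) || !all(all_ids %in% names(exposure))) {
    abort("`exposure` must be named and cover every sample id.")
  }
  paired <- intersect(ids1, ids2)
  if (length(paired) < 2L) {
    abort("fewer than 2 individuals observed at both timepoints.")
  }

  cov_block <- function(covs, mat, label) {
    if (is.null(covs)) return(NULL)
    covs <- tibble::as_tibble(covs)
    if ("sample_id" %in% names(covs)) {
      if (!identical(covs$sample_id, rownames(mat))) {
        abort(sprintf("covariates_%s rows are not aligned with res_%s.",
                      label, label))
      }
      covs$sample_id <- NULL
    }
    if (nrow(covs) != nrow(mat)) {
      abort(sprintf("covariates_%s and res_%s differ in rows.", label, label))
    }
    covs
  }
  c1 <- cov_block(covariates_t1, res_t1, "t1")
  c2 <- cov_block(covariates_t2, res_t2, "t2")
  if (xor(is.null(c1), is.null(c2)) ||
      (!is.null(c1) && !identical(names(c1), names(c2)))) {
    abort("study covariate columns must match between timepoints.")
  }

  # long design shared by all CpGs
  time <- c(rep(0L, length(ids1)), rep(1L, length(ids2)))
  id_long <- c(ids1, ids2)
  expo <- unname(exposure[id_long])
  base <- data.frame(exposure = expo, time = time)
  if (!is.null(c1)) {
    base <- cbind(base, rbind(as.data.frame(c1), as.data.frame(c2)))
  }
  X <- model.matrix(~ exposure * time + ., data = base)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(sprintf("stacked design is rank deficient (column%s %s).",
                  if (length(bad) > 1L) "s" else "",
                  paste(bad, collapse = ", ")))
  }

  # index bookkeeping for whitening: paired rows vs singletons
  row_t1 <- seq_along(ids1)
  row_t2 <- length(ids1) + seq_along(ids2)
  p1 <- row_t1[match(paired, ids1)]
  p2 <- row_t2[match(paired, ids2)]
  s1 <- setdiff(row_t1, p1)
  s2 <- setdiff(row_t2, p2)

  j_exp <- match("exposure", colnames(X))
  j_int <- match("exposure:time", colnames(X))
  if (is.na(j_int)) j_int <- match("time:exposure", colnames(X))

  fit_one <- function(y) {
    beta <- qr.coef(qx, y)
    sig1 <- 1; sig2 <- 1; r <- 0
    converged <- FALSE
    Xw <- NULL; yw <- NULL
    for (it in seq_len(max_iter)) {
      e <- y - drop(X %*% beta)
      sig1 <- sqrt(mean(e[row_t1]^2))
      sig2 <- sqrt(mean(e[row_t2]^2))
      if (sig1 <= 0 || sig2 <= 0) {
        abort("degenerate (zero) residual variance in the GLS stage.")
      }
      r <- mean(e[p1] * e[p2]) / (sig1 * sig2)
      r <- max(min(r, 0.999), -0.999)
      # whiten: paired blocks share the 2x2 covariance; lower Cholesky
      l11 <- sig1
      l21 <- r * sig2
      l22 <- sig2 * sqrt(1 - r^2)
      Xw <- X; yw <- y
      Xw[p1, ] <- X[p1, , drop = FALSE] / l11
      yw[p1] <- y[p1] / l11
      Xw[p2, ] <- (X[p2, , drop = FALSE] - l21 * Xw[p1, , drop = FALSE]) / l22
      yw[p2] <- (y[p2] - l21 * yw[p1]) / l22
      if (length(s1) > 0) {
        Xw[s1, ] <- X[s1, , drop = FALSE] / sig1
        yw[s1] <- y[s1] / sig1
      }
      if (length(s2) > 0) {
        Xw[s2, ] <- X[s2, , drop = FALSE] / sig2
        yw[s2] <- y[s2] / sig2
      }
      qw <- qr(Xw)
      beta_new <- qr.coef(qw, yw)
      delta <- max(abs(beta_new - beta)) /
        max(max(abs(beta)), .Machine$double.eps)
      beta <- beta_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    qw <- qr(Xw)
    Rw <- qr.R(qw)
    V <- chol2inv(Rw)
    unpiv <- order(qw$pivot)
    V <- V[unpiv, unpiv, drop = FALSE]
    b1 <- unname(beta[j_exp])
    bi <- unname(beta[j_int])
    se1 <- sqrt(V[j_exp, j_exp])
    sei <- sqrt(V[j_int, j_int])
    b2 <- b1 + bi
    se2 <- sqrt(V[j_exp, j_exp] + V[j_int, j_int] + 2 * V[j_exp, j_int])
    list(beta_t1 = b1, se_t1 = se1, beta_t2 = b2, se_t2 = se2,
         interaction_beta = bi, interaction_se = sei,
         equality_pval = two_sided_normal_p(bi / sei),
         resid_sd_t1 = sig1, resid_sd_t2 = sig2, resid_corr = r,
         converged = converged)
  }

  cpgs <- colnames(res_t1)
  rows <- purrr::map(cpgs, function(cg) {
    y <- c(res_t1[, cg], res_t2[, cg])
    out <- fit_one(y)
    if (!out$converged) {
      warn(sprintf("feasible GLS did not converge for %s within %d iterations.",
                   cg, max_iter))
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      cpg_id = cpgs,
      n_individuals = length(all_ids),
      n_paired = length(paired),
      .before = 1
    )
}

#' Two-stage longitudinal persistence analysis of exposure effects
#'
#' Convenience wrapper around [residualize()] and
#' [fit_gls_persistence()]: methylation at each timepoint is regressed
#' on the technical and cell-type covariates, and the residuals enter
#' the stacked exposure x timepoint GLS with study covariates. A
#' one-stage option includes the technical covariates directly in the
#' GLS instead (statistically cleaner; the two-stage route is the
#' default published procedure).
#'
#' @param bundle_t1,bundle_t2 `cohort_bundle`s for the two timepoints
#'   sharing sample ids.
#' @param exposure_column Exposure column name (time-invariant).
#' @param technical_covariates Covariate columns removed in the
#'   residualization stage (technical PCs, cell proportions).
#' @param study_covariates Covariate columns entering the GLS stage.
#' @param one_stage If `TRUE`, skip residualization and put the
#'   technical covariates in the GLS design.
#' @inheritParams fit_gls_persistence
#' @return A tibble of persistence records (see
#'   [fit_gls_persistence()]).
#' @export
persistence_analysis <- function(bundle_t1, bundle_t2,
                                 exposure_column = "maternal_smoking",
                                 technical_covariates = character(),
                                 study_covariates = character(),
                                 one_stage = FALSE,
                                 max_iter = 100, tol = 1e-8) {
  check_bundle(bundle_t1)
  check_bundle(bundle_t2)
  pick <- function(bundle, cols) {
    assert_columns(bundle$covariates, cols, "covariate table")
    bundle$covariates[, c("sample_id", cols), drop = FALSE]
  }
  expo <- setNames(
    c(bundle_t1$covariates[[exposure_column]],
      bundle_t2$covariates[[exposure_column]]),
    c(bundle_t1$covariates$sample_id, bundle_t2$covariates$sample_id)
  )
  if (one_stage) {
    gls_cols <- unique(c(study_covariates, technical_covariates))
    fit_gls_persistence(
      scale(bundle_t1$methylation, scale = FALSE),
      scale(bundle_t2$methylation, scale = FALSE),
      expo,
      pick(bundle_t1, gls_cols), pick(bundle_t2, gls_cols),
      max_iter = max_iter, tol = tol
    )
  } else {
    r1 <- residualize(bundle_t1$methylation,
                      pick(bundle_t1, technical_covariates))
    r2 <- residualize(bundle_t2$methylation,
                      pick(bundle_t2, technical_covariates))
    fit_gls_persistence(
      r1, r2, expo,
      if (length(study_covariates) > 0) pick(bundle_t1, study_covariates),
      if (length(study_covariates) > 0) pick(bundle_t2, study_covariates),
      max_iter = max_iter, tol = tol
    )
  }
}
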