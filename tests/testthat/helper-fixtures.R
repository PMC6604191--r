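# Fixtures built in code, shared across test files.

# A tiny deterministic cohort: 6 samples, 3 CpGs, hand-enterable numbers.
toy_bundle <- function() {
  meth <- matrix(
    c(0.50, 0.52, 0.55, 0.61, 0.58, 0.64,
      0.30, 0.33, 0.31, 0.29, 0.35, 0.32,
      0.70, 0.69, 0.72, 0.71, 0.68, 0.73),
    nrow = 6, ncol = 3,
    dimnames = list(paste0("s", 1:6), paste0("cpg_", 1:3))
  )
  covs <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    maternal_smoking = c(0L, 0L, 0L, 1L, 1L, 1L),
    cigs_per_day = c(0, 0, 0, 2, 5, 3),
    paternal_smoking = c(0L, 1L, 0L, 1L, 0L, 1L),
    own_smoking = c(0L, 0L, 1L, 0L, 1L, 0L),
    sex = c(0L, 1L, 0L, 1L, 0L, 1L),
    bmi = c(22.1, 24.3, 26.0, 23.5, 25.2, 27.8)
  )
  ann <- tibble::tibble(
    cpg_id = paste0("cpg_", 1:3),
    chromosome = c("1", "1", "2"),
    position = c(1000L, 500000L, 1000L),
    gene = c("GENE1", "GENE1", "GENE2")
  )
  cohort_bundle(meth, ann, covs)
}

# Independent normal-equations OLS oracle: beta, se and t-based p for
# one focal column, computed from explicit matrix inverses.
ols_oracle <- function(X, y, focal) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  j <- match(focal, colnames(X))
  se <- sqrt(sigma2 * XtX_inv[j, j])
  b <- beta[j]
  list(beta = b, se = se, pval = 2 * pt(-abs(b / se), df))
}

# A noiseless generator configuration: planted effects only, all other
# sources of variation switched off.
noiseless_config <- function(..., seed = 1L) {
  sim_config(noise_sd = 0, covariate_loading_sd = 0, cell_loading_sd = 0,
             seed = seed, ...)
}

# Quick null-free EWAS dataset: exposure effect planted at cpg_1.
planted_sim <- function(n = 400, effect = 0.05, seed = 1L, ...) {
  simulate_cohort(sim_config(
    n_samples = n, n_cpgs = 5,
    effect_sizes = c(cpg_1 = effect), seed = seed, ...
  ))
}

# Linear mediation data with known paths: exposure -> mediator (a),
# mediator -> outcome (b), direct exposure -> outcome path, one
# confounder-free covariate in both models.
gen_mediation_data <- function(n, a = 0.5, b = 0.4, direct = 0.3,
                               seed = 1, p_exposed = 0.3) {
  set.seed(seed)
  x <- rbinom(n, 1, p_exposed)
  cov1 <- rnorm(n)
  m <- a * x + 0.2 * cov1 + rnorm(n)
  y <- direct * x + b * m - 0.1 * cov1 + rnorm(n)
  tibble::tibble(x = x, m = m, y = y, cov1 = cov1)
}

# Exhaustive clumping oracle for <= 8 SNPs: among all subsets that are
# (a) below the p threshold, (b) pairwise compatible under the
# window+r2 rule, and (c) maximal (no further candidate can be added),
# pick the one whose members appear earliest in the priority order
# (ascending p, then snp id). Independent of the greedy implementation.
clump_oracle <- function(mqtl, ld, p_threshold, window_bp, r2_threshold) {
  cand <- mqtl[mqtl$pval < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$snp), , drop = FALSE]
  k <- nrow(cand)
  if (k == 0L) return(character())
  half <- window_bp / 2
  compatible <- function(i, j) {
    near <- cand$chr[i] == cand$chr[j] &&
      abs(cand$pos[i] - cand$pos[j]) <= half
    !(near && ld[cand$snp[i], cand$snp[j]]^2 >= r2_threshold)
  }
  subsets <- unlist(lapply(seq_len(k), function(s)
    utils::combn(k, s, simplify = FALSE)), recursive = FALSE)
  valid <- Filter(function(S) {
    if (length(S) > 1) {
      pairs <- utils::combn(S, 2)
      if (!all(apply(pairs, 2, function(p) compatible(p[1], p[2]))))
        return(FALSE)
    }
    # maximality
    for (j in setdiff(seq_len(k), S)) {
      if (all(vapply(S, function(i) compatible(i, j), logical(1))))
        return(FALSE)
    }
    TRUE
  }, subsets)
  # earliest in priority order: lexicographically smallest index vector
  keys <- vapply(valid, function(S) paste(sprintf("%03d", S), collapse = ","),
                 character(1))
  cand$snp[valid[[order(keys)[1]]]]
}
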