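# Internal helpers shared across stages.

#' @importFrom rlang abort warn inform .data
#' @importFrom stats pnorm pt qnorm quantile rnorm rbinom runif rgamma ppois
#'   qpois complete.cases model.matrix sd var coef residuals fitted plogis
#'   setNames p.adjust lm glm binomial vcov cor
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", field,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, field, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < minimum) {
    abort(sprintf("`%s` must be an integer >= %d.", field, minimum))
  }
  as.integer(x)
}

assert_columns <- function(df, required, what = "input table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1L) "s" else "",
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
  invisible(df)
}

assert_no_duplicates <- function(ids, what = "id") {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicated %s%s: %s.", what, if (length(dup) > 1L) "s" else "",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(ids)
}

# Deterministically spawn per-stage seeds from one master seed, so that
# individual stages can be rerun in isolation yet reproducibly.
spawn_seeds <- function(master_seed, n) {
  master_seed <- assert_count(master_seed, "seed", minimum = 0L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Multi-response OLS: one design matrix, many outcome columns.
# Returns, for a focal coefficient, its estimate, standard error and
# two-sided t-test p-value per outcome column, plus residuals on request.
# The QR is computed once; rank deficiency is reported with the offending
# columns (via the pivoted QR).
ols_many <- function(X, Y, focal, keep_residuals = FALSE) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2L) {
    abort(sprintf(
      "too few complete cases (%d) for %d model parameters; need at least %d.",
      n, p, p + 2L
    ))
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    abort(sprintf(
      "design matrix is rank deficient; offending column%s: %s.",
      if (length(bad) > 1L) "s" else "", paste(bad, collapse = ", ")
    ))
  }
  coefs <- qr.coef(qx, Y)                       # p x m
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  # undo the pivot so rows of XtX_inv align with columns of X
  unpiv <- order(qx$pivot)
  XtX_inv <- XtX_inv[unpiv, unpiv, drop = FALSE]
  j <- match(focal, colnames(X))
  if (is.na(j)) abort(sprintf("focal term '%s' not in the design.", focal))
  beta <- coefs[j, ]
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = df)
  out <- list(
    beta = unname(beta), se = unname(se), pval = unname(pval),
    df = df, n = n, coefs = coefs, XtX_inv = XtX_inv, sigma2 = sigma2
  )
  if (keep_residuals) out$residuals <- res
  out
}

# Build a design matrix from a covariate tibble: intercept + exposure +
# covariates, with factors expanded. Used by the EWAS-style fits.
build_design <- function(covariates, exposure_column, covariate_columns) {
  assert_columns(covariates, c(exposure_column, covariate_columns),
                 "covariate table")
  cols <- unique(c(exposure_column, covariate_columns))
  dat <- as.data.frame(covariates[, cols, drop = FALSE])
  # guard against constant columns, which silently break interpretation
  for (cl in cols) {
    v <- dat[[cl]]
    if (is.numeric(v) && length(unique(v[is.finite(v)])) < 2L) {
      abort(sprintf("column '%s' is constant; model is uninformative.", cl))
    }
  }
  cc <- complete.cases(dat)
  X <- model.matrix(~., data = dat[cc, , drop = FALSE])
  list(X = X, complete = which(cc))
}

two_sided_normal_p <- function(z) 2 * pnorm(-abs(z))

format_num <- function(x) formatC(x, digits = 17, format = "g")
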