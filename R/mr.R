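COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1]) == a2
}

#' LD correlation matrix from a genotype dosage matrix
#'
#' @param genotypes Samples x SNPs numeric matrix of allele dosages
#'   (0-2) with SNP ids as column names.
#' @return The SNP correlation matrix (unit diagonal).
#' @export
ld_from_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes) || is.null(colnames(genotypes))) {
    abort("`genotypes` must be a matrix with SNP ids as column names.")
  }
  cor(genotypes)
}

#' Select and clump mQTL instruments per CpG
#'
#' For each CpG, candidate SNPs are those with mQTL p-value strictly
#' below `p_threshold`. Candidates are processed greedily by ascending
#' p-value: a SNP is retained unless it lies within `window_bp / 2`
#' base pairs of an already-retained SNP (same chromosome) *and* has
#' LD `r^2 >= r2_threshold` with it. Dropped SNPs are recorded in an
#' exclusion log with a reason (`"pval"` for candidates above the
#' threshold, `"ld"` for clumped ones).
#'
#' @param mqtl Tibble of mQTL summary statistics: columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `cpg`, and optionally `chr`, `pos` (without positions the distance
#'   condition is treated as satisfied, i.e. LD-only clumping).
#' @param ld Square SNP correlation matrix (ids in dimnames) covering
#'   every candidate SNP.
#' @param p_threshold Instrument p-value threshold (default 1e-7).
#' @param window_bp Clumping window width in base pairs (default
#'   1,000,000).
#' @param r2_threshold LD r-squared above which a nearby SNP is clumped
#'   away (default 0.001).
#' @return A tibble with one row per CpG that has at least one retained
#'   instrument: `cpg_id`, `n_snps`, `snps` (list-column of retained
#'   mQTL rows), `exclusions` (list-column tibble snp/reason).
#' @export
select_and_clump <- function(mqtl, ld, p_threshold = 1e-7,
                             window_bp = 1e6, r2_threshold = 0.001) {
  mqtl <- tibble::as_tibble(mqtl)
  assert_columns(mqtl, c("snp", "effect_allele", "other_allele", "eaf",
                         "beta", "se", "pval", "cpg"), "`mqtl`")
  assert_scalar_number(p_threshold, "p_threshold", 0, 1,
                       strict_lower = TRUE)
  assert_scalar_number(window_bp, "window_bp", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  if (!is.matrix(ld) || is.null(rownames(ld))) {
    abort("`ld` must be a square matrix with SNP ids in dimnames.")
  }
  absent <- setdiff(unique(mqtl$snp), rownames(ld))
  if (length(absent) > 0L) {
    abort(sprintf("SNP%s absent from the LD matrix: %s.",
                  if (length(absent) > 1L) "s" else "",
                  paste(head(absent, 5L), collapse = ", ")))
  }
  has_pos <- all(c("chr", "pos") %in% names(mqtl))
  half <- window_bp / 2

  per_cpg <- split(mqtl, mqtl$cpg)
  rows <- purrr::imap(per_cpg, function(tb, cg) {
    tb <- dplyr::arrange(tb, .data$pval, .data$snp)
    excl <- list()
    cand <- tb[tb$pval < p_threshold, , drop = FALSE]
    over <- tb[tb$pval >= p_threshold, , drop = FALSE]
    if (nrow(over) > 0L) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(snp = over$snp, reason = "pval")
    }
    kept <- cand[0, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, , drop = FALSE]
      drop_it <- FALSE
      if (nrow(kept) > 0L) {
        r2 <- ld[row$snp, kept$snp]^2
        near <- if (has_pos) {
          kept$chr == row$chr & abs(kept$pos - row$pos) <= half
        } else {
          rep(TRUE, nrow(kept))
        }
        drop_it <- any(near & r2 >= r2_threshold)
      }
      if (drop_it) {
        excl[[length(excl) + 1L]] <-
          tibble::tibble(snp = row$snp, reason = "ld")
      } else {
        kept <- dplyr::bind_rows(kept, row)
      }
    }
    if (nrow(kept) == 0L) return(NULL)
    log <- if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(snp = character(), reason = character())
    tibble::tibble(
      cpg_id = cg,
      n_snps = nrow(kept),
      snps = list(kept),
      exclusions = list(log)
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Harmonize exposure and outcome summary statistics to the same allele
#'
#' Aligns each outcome record to the effect allele of the matching
#' exposure record: swapped alleles flip the outcome beta and complement
#' its allele frequency; strand flips (A<->T, C<->G relabeling) are
#' resolved via allele complements. Palindromic SNPs (A/T or C/G) with
#' exposure allele frequency in \[0.42, 0.58\] are excluded as
#' strand-ambiguous; palindromic SNPs outside that band are oriented by
#' comparing allele frequencies. Allele sets that neither match, swap,
#' nor strand-flip are excluded.
#'
#' @param exposure,outcome Summary-statistic tibbles sharing `snp`
#'   (columns `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`).
#' @return A list: `harmonized` (joined tibble with exposure columns
#'   suffixed `_exp` and aligned outcome columns suffixed `_out`) and
#'   `exclusions` (tibble snp/reason with reasons
#'   `"palindromic-ambiguous"`, `"allele-mismatch"`, `"missing-outcome"`).
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
  assert_columns(exposure, need, "`exposure`")
  assert_columns(outcome, need, "`outcome`")
  excl <- list()
  out_rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    oc <- outcome[outcome$snp == ex$snp, , drop = FALSE]
    if (nrow(oc) == 0L) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(snp = ex$snp, reason = "missing-outcome")
      next
    }
    oc <- oc[1, ]
    ea <- ex$effect_allele; oa <- ex$other_allele
    pe <- is_palindromic(ea, oa)
    if (pe && ex$eaf >= 0.42 && ex$eaf <= 0.58) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(snp = ex$snp, reason = "palindromic-ambiguous")
      next
    }
    flip <- NA
    if (oc$effect_allele == ea && oc$other_allele == oa) {
      flip <- FALSE
    } else if (oc$effect_allele == oa && oc$other_allele == ea) {
      flip <- TRUE
    } else if (!pe &&
               unname(COMPLEMENT[oc$effect_allele]) == ea &&
               unname(COMPLEMENT[oc$other_allele]) == oa) {
      flip <- FALSE
    } else if (!pe &&
               unname(COMPLEMENT[oc$effect_allele]) == oa &&
               unname(COMPLEMENT[oc$other_allele]) == ea) {
      flip <- TRUE
    } else {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(snp = ex$snp, reason = "allele-mismatch")
      next
    }
    if (pe) {
      # unambiguous palindrome: orient by allele-frequency concordance
      flip <- (ex$eaf - 0.5) * (oc$eaf - 0.5) < 0
    }
    b_out <- if (flip) -oc$beta else oc$beta
    eaf_out <- if (flip) 1 - oc$eaf else oc$eaf
    out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
      snp = ex$snp,
      effect_allele = ea, other_allele = oa,
      eaf_exp = ex$eaf, beta_exp = ex$beta, se_exp = ex$se,
      pval_exp = if ("pval" %in% names(ex)) ex$pval else NA_real_,
      eaf_out = eaf_out, beta_out = b_out, se_out = oc$se,
      pval_out = if ("pval" %in% names(oc)) oc$pval else NA_real_
    )
  }
  empty_log <- tibble::tibble(snp = character(), reason = character())
  list(
    harmonized = dplyr::bind_rows(out_rows),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else empty_log
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome is the SNP-outcome
#' effect divided by the SNP-exposure effect. The default standard
#' error is first order (`se_out / |b_exp|`, instrument uncertainty
#' ignored, the convention of standard two-sample MR practice); the
#' full delta-method alternative also propagates the instrument
#' standard error.
#'
#' @param b_exp,se_exp SNP -> exposure effect and standard error.
#' @param b_out,se_out SNP -> outcome effect and standard error.
#' @param se_method `"first-order"` (default) or `"delta"`.
#' @return A one-row tibble: `method`, `beta`, `se`, `pval`, `n_snps`.
#' @export
wald_ratio <- function(b_exp, se_exp, b_out, se_out,
                       se_method = c("first-order", "delta")) {
  se_method <- match.arg(se_method)
  if (!is.finite(b_exp) || b_exp == 0) {
    abort("SNP -> exposure effect is zero; Wald ratio undefined (weak/null instrument).")
  }
  beta <- b_out / b_exp
  se <- if (se_method == "first-order") {
    se_out / abs(b_exp)
  } else {
    sqrt(se_out^2 / b_exp^2 + b_out^2 * se_exp^2 / b_exp^4)
  }
  tibble::tibble(
    method = "wald_ratio", beta = beta, se = se,
    pval = two_sided_normal_p(beta / se), n_snps = 1L
  )
}

#' Inverse-variance weighted causal estimate from multiple instruments
#'
#' Combines per-instrument associations as
#' `beta = sum(b_exp * b_out / se_out^2) / sum(b_exp^2 / se_out^2)` with
#' `se = (sum(b_exp^2 / se_out^2))^(-1/2)`; equivalent to a
#' zero-intercept weighted regression of outcome effects on exposure
#' effects with weights `1/se_out^2`, and to inverse-variance pooling of
#' the per-instrument Wald ratios with first-order weights.
#'
#' @param b_exp,b_out Vectors of harmonized SNP -> exposure and
#'   SNP -> outcome effects (length >= 2).
#' @param se_out Vector of SNP -> outcome standard errors.
#' @return A one-row tibble: `method`, `beta`, `se`, `pval`, `n_snps`.
#' @export
ivw_mr <- function(b_exp, b_out, se_out) {
  k <- length(b_exp)
  if (k < 2L) {
    abort("fewer than 2 instruments; use wald_ratio() for a single SNP.")
  }
  if (length(b_out) != k || length(se_out) != k) {
    abort("`b_exp`, `b_out`, `se_out` must have equal length.")
  }
  w <- 1 / se_out^2
  denom <- sum(b_exp^2 * w)
  beta <- sum(b_exp * b_out * w) / denom
  se <- 1 / sqrt(denom)
  tibble::tibble(
    method = "ivw", beta = beta, se = se,
    pval = two_sided_normal_p(beta / se), n_snps = as.integer(k)
  )
}

#' Two-sample MR scan of CpGs against many disease outcomes
#'
#' For every (CpG, trait) pair with at least one usable harmonized
#' instrument, estimates the causal effect of methylation on the trait
#' by Wald ratio (single instrument) or IVW (two or more), then applies
#' Benjamini-Hochberg correction across all pairs in the scan.
#'
#' @param instruments Output of [select_and_clump()].
#' @param outcomes A tibble of GWAS summary statistics for one or more
#'   traits (columns as in [harmonize()] plus `trait_id`).
#' @param se_method Wald-ratio standard error method (see
#'   [wald_ratio()]).
#' @param fdr_alpha Significance level on the adjusted p-value for the
#'   `significant` flag (default 0.05).
#' @param consistency_tables Optional named list of mQTL tables from
#'   other timepoints; instruments whose SNP -> CpG effect changes sign
#'   across tables are dropped (reason `"sign-inconsistent"`).
#' @return A tibble with one row per estimable pair: `cpg_id`,
#'   `trait_id`, `method`, `beta`, `se`, `pval`, `fdr_pval`, `n_snps`,
#'   `significant`. Pairs with no usable instrument are skipped and
#'   recorded in the `"skipped"` attribute.
#' @export
mr_scan <- function(instruments, outcomes, se_method = "first-order",
                    fdr_alpha = 0.05, consistency_tables = NULL) {
  outcomes <- tibble::as_tibble(outcomes)
  assert_columns(outcomes, c("snp", "effect_allele", "other_allele",
                             "eaf", "beta", "se", "trait_id"),
                 "`outcomes`")
  traits <- unique(outcomes$trait_id)
  skipped <- list()
  rows <- list()
  for (i in seq_len(nrow(instruments))) {
    inst <- instruments$snps[[i]]
    cg <- instruments$cpg_id[i]
    if (!is.null(consistency_tables)) {
      ok <- purrr::map_lgl(inst$snp, function(s) {
        signs <- purrr::map_dbl(consistency_tables, function(tb) {
          hit <- tb[tb$snp == s & tb$cpg == cg, , drop = FALSE]
          if (nrow(hit) == 0L) return(NA_real_)
          sign(hit$beta[1])
        })
        signs <- signs[!is.na(signs)]
        all(signs == sign(inst$beta[inst$snp == s][1]))
      })
      inst <- inst[ok, , drop = FALSE]
      if (nrow(inst) == 0L) {
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(cpg_id = cg, trait_id = NA_character_,
                         reason = "sign-inconsistent")
        next
      }
    }
    for (tr in traits) {
      oc <- outcomes[outcomes$trait_id == tr, , drop = FALSE]
      h <- harmonize(inst, oc)$harmonized
      if (nrow(h) == 0L) {
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(cpg_id = cg, trait_id = tr,
                         reason = "no-overlapping-instruments")
        next
      }
      est <- if (nrow(h) == 1L) {
        wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out,
                   se_method = se_method)
      } else {
        ivw_mr(h$beta_exp, h$beta_out, h$se_out)
      }
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(est, cpg_id = cg, trait_id = tr, .before = 1)
    }
  }
  if (length(rows) == 0L) {
    abort("no (CpG, trait) pair was estimable.")
  }
  out <- dplyr::bind_rows(rows)
  out$fdr_pval <- bh_fdr(out$pval)
  out$significant <- out$fdr_pval < fdr_alpha
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out[, c("cpg_id", "trait_id", "method", "beta", "se", "pval",
          "fdr_pval", "n_snps", "significant")]
}
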