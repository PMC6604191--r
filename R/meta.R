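#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools per-study EWAS records per CpG with weights `1/se^2`:
#' the combined effect is the weighted mean of study effects and the
#' combined standard error is `(sum of weights)^(-1/2)`. CpGs present in
#' only a subset of studies are meta-analyzed over that subset, with the
#' number of contributing studies recorded. Meta-level p-values come
#' from the standard normal (the conventional choice for inverse
#' variance weighted pooling; per-study degrees of freedom are not
#' propagated). Cochran's Q is computed and reported but never gates
#' inclusion.
#'
#' @param studies A list of per-study record tibbles (each with columns
#'   `cpg_id`, `beta`, `se`), optionally named by study.
#' @return A tibble with one row per CpG: `cpg_id`, `beta`, `se`,
#'   `z`, `pval`, `k_studies`, `direction` (one `+`/`-` per contributing
#'   study, in study order), `q` and `q_pval` (heterogeneity, reported
#'   only).
#' @export
ivw_meta <- function(studies) {
  if (inherits(studies, "data.frame")) studies <- list(studies)
  if (!is.list(studies) || length(studies) == 0L) {
    abort("`studies` must be a non-empty list of per-study record tables.")
  }
  study_names <- names(studies) %||% rep("", length(studies))
  study_names <- ifelse(study_names == "",
                        paste0("study_", seq_along(studies)), study_names)
  stacked <- purrr::map2_dfr(studies, study_names, function(tb, nm) {
    tb <- tibble::as_tibble(tb)
    assert_columns(tb, c("cpg_id", "beta", "se"),
                   sprintf("study '%s'", nm))
    if (any(!is.finite(tb$se)) || any(tb$se <= 0)) {
      abort(sprintf("study '%s' has zero, negative or non-finite se.", nm))
    }
    tibble::tibble(cpg_id = tb$cpg_id, beta = tb$beta, se = tb$se,
                   study = nm)
  })
  stacked$study <- factor(stacked$study, levels = study_names)
  stacked <- dplyr::arrange(stacked, .data$cpg_id, .data$study)
  pooled <- stacked |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::group_modify(function(g, key) {
      w <- 1 / g$se^2
      b <- sum(w * g$beta) / sum(w)
      tibble::tibble(
        beta = b,
        se = 1 / sqrt(sum(w)),
        k_studies = nrow(g),
        direction = paste(ifelse(g$beta >= 0, "+", "-"), collapse = ""),
        q = sum(w * (g$beta - b)^2)
      )
    }) |>
    dplyr::ungroup()
  pooled |>
    dplyr::mutate(
      z = .data$beta / .data$se,
      pval = two_sided_normal_p(.data$z),
      q_pval = ifelse(.data$k_studies > 1L,
                      stats::pchisq(.data$q, df = pmax(.data$k_studies - 1L, 1L),
                                    lower.tail = FALSE),
                      NA_real_)
    ) |>
    dplyr::select("cpg_id", "beta", "se", "z", "pval", "k_studies",
                  "direction", "q", "q_pval")
}

#' Filter meta-analysis records at a significance threshold
#'
#' Retains records with `pval` strictly below `alpha`. The default
#' threshold of 1e-7 corresponds approximately to a Bonferroni-corrected
#' level of 0.05 for 450,000 independent tests.
#'
#' @param meta A tibble with a `pval` column.
#' @param alpha Significance level in (0, 1); strict inequality.
#' @return The rows of `meta` with `pval < alpha`.
#' @export
apply_threshold <- function(meta, alpha = 1e-7) {
  assert_scalar_number(alpha, "alpha", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  meta <- tibble::as_tibble(meta)
  assert_columns(meta, "pval", "`meta`")
  meta[meta$pval < alpha, , drop = FALSE]
}

#' Greedy leading-CpG region pruning
#'
#' Partitions significant CpGs into genomic regions: repeatedly take the
#' unassigned CpG with the smallest p-value as a region leader and
#' absorb every unassigned CpG on its chromosome within `window / 2`
#' base pairs of its position ("1-Mb window centered on the CpG with the
#' strongest association"), until none remain. Ties in p-value are
#' broken by descending `|z|` (or `|beta/se|`) when available -- printed
#' p-values often carry fewer digits than the underlying statistic --
#' then by ascending chromosome and position, so the partition is
#' deterministic under input permutation.
#'
#' @param significant A tibble of significant records joined to
#'   annotation: columns `cpg_id`, `pval`, `chromosome`, `position`
#'   (1-based), optionally `z` or `beta` and `se` for tie-breaking.
#' @param window Full window width in base pairs (default 1,000,000);
#'   members lie within `window / 2` of their leader.
#' @return A tibble with one row per region: `region_id`, `chromosome`,
#'   `leading_cpg`, `n_members`, `members` (list-column of member CpG
#'   ids including the leader), `window_halfwidth`.
#' @export
select_leading_cpgs <- function(significant, window = 1e6) {
  assert_scalar_number(window, "window", 0, Inf, strict_lower = TRUE)
  significant <- tibble::as_tibble(significant)
  assert_columns(significant, c("cpg_id", "pval", "chromosome", "position"),
                 "`significant`")
  miss <- significant$cpg_id[!is.finite(significant$position) |
                               is.na(significant$chromosome)]
  if (length(miss) > 0L) {
    abort(sprintf("missing annotation for significant CpG%s: %s.",
                  if (length(miss) > 1L) "s" else "",
                  paste(head(miss, 5L), collapse = ", ")))
  }
  assert_no_duplicates(significant$cpg_id, "cpg_id")
  if (nrow(significant) == 0L) {
    return(tibble::tibble(
      region_id = character(), chromosome = character(),
      leading_cpg = character(), n_members = integer(),
      members = list(), window_halfwidth = numeric()
    ))
  }
  zmag <- if ("z" %in% names(significant)) {
    abs(significant$z)
  } else if (all(c("beta", "se") %in% names(significant))) {
    abs(significant$beta / significant$se)
  } else {
    rep(0, nrow(significant))
  }
  ord <- order(significant$pval, -zmag,
               as.character(significant$chromosome), significant$position)
  df <- significant[ord, , drop = FALSE]
  half <- window / 2
  assigned <- rep(FALSE, nrow(df))
  regions <- list()
  while (!all(assigned)) {
    lead <- which(!assigned)[1]
    members <- which(!assigned &
                       df$chromosome == df$chromosome[lead] &
                       abs(df$position - df$position[lead]) <= half)
    assigned[members] <- TRUE
    regions[[length(regions) + 1L]] <- tibble::tibble(
      chromosome = as.character(df$chromosome[lead]),
      leading_cpg = df$cpg_id[lead],
      n_members = length(members),
      members = list(df$cpg_id[sort(members)]),
      window_halfwidth = half
    )
  }
  out <- dplyr::bind_rows(regions)
  out$region_id <- sprintf("region_%03d", seq_len(nrow(out)))
  out[, c("region_id", "chromosome", "leading_cpg", "n_members",
          "members", "window_halfwidth")]
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]), monotone
#' nondecreasing in the raw p-values and capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must be probabilities in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}
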