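# ggplot2 displays for the main result types. These are deliberately
# plain: effect/CI text reports are the primary output of the pipeline.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of meta-analysis results
#'
#' @param meta A tibble from [ivw_meta()].
#' @param alpha Significance threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_meta_volcano <- function(meta, alpha = 1e-7) {
  ggplot2::ggplot(meta, ggplot2::aes(x = .data$beta,
                                     y = -log10(.data$pval))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = "effect (beta-value units)",
      y = expression(-log[10](italic(P))),
      title = "Inverse-variance weighted meta-analysis"
    )
}

#' Concordance of effect estimates between two analyses
#'
#' Scatter of effect sizes with 95% confidence bars from two record
#' tables sharing CpGs, e.g. the full meta-analysis against the
#' never-smoker subset, or maternal against paternal exposure.
#'
#' @param records_x,records_y Tibbles with `cpg_id`, `beta`, `se`.
#' @param labels Axis labels, length 2.
#' @return A ggplot object.
#' @export
plot_concordance <- function(records_x, records_y,
                             labels = c("all participants",
                                        "never-smokers")) {
  joined <- dplyr::inner_join(
    records_x[, c("cpg_id", "beta", "se")],
    records_y[, c("cpg_id", "beta", "se")],
    by = "cpg_id", suffix = c("_x", "_y")
  )
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_y - 1.96 * .data$se_y,
      ymax = .data$beta_y + 1.96 * .data$se_y), width = 0, alpha = 0.4) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_x - 1.96 * .data$se_x,
      xmax = .data$beta_x + 1.96 * .data$se_x), height = 0, alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = labels[1], y = labels[2])
}

#' Forest-style display of per-timepoint persistence estimates
#'
#' @param records A tibble from [fit_gls_persistence()].
#' @return A ggplot object.
#' @export
plot_persistence <- function(records) {
  long <- dplyr::bind_rows(
    tibble::tibble(cpg_id = records$cpg_id, timepoint = "t1",
                   beta = records$beta_t1, se = records$se_t1),
    tibble::tibble(cpg_id = records$cpg_id, timepoint = "t2",
                   beta = records$beta_t2, se = records$se_t2)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, y = .data$cpg_id,
                                     colour = .data$timepoint)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta - 1.96 * .data$se,
      xmax = .data$beta + 1.96 * .data$se),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "exposure effect on residualized methylation",
                  y = NULL, colour = "timepoint")
}

#' Estimate-and-interval display of a mediation record
#'
#' @param x A `mediation_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_record <- function(x, ...) {
  d <- tidy.mediation_record(x)
  d <- d[d$term != "prop_mediated", ]
  d$term <- factor(d$term, levels = c("total_effect", "ade", "acme"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "effect estimate (95% interval)", y = NULL)
}
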