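#' Pipeline configuration
#'
#' Collects every input and threshold of the end-to-end run in one
#' validated object: the number and size of (synthetic) cohorts or the
#' directories of pre-existing cohort bundles, covariate lists, the
#' significance threshold, region window, clumping parameters, FDR
#' level, mediation draw count, and the master seed from which each
#' stage's seed is deterministically spawned.
#'
#' @param out_dir Output directory for stage results.
#' @param seed Master seed.
#' @param n_cohorts Number of cohorts to simulate (ignored when
#'   `cohort_dirs` is given).
#' @param cohort_dirs Optional character vector of directories holding
#'   cohort bundle TSVs (read with [read_cohort_bundle()]); all must
#'   exist before the run starts.
#' @param sim Optional list of arguments passed to [sim_config()] for
#'   each simulated cohort (the per-cohort seed is supplied by the
#'   pipeline).
#' @param covariates Covariate columns for the EWAS models.
#' @param technical_covariates Covariate columns removed in the
#'   persistence residualization stage.
#' @param n_timepoint2_cohorts How many of the first cohorts get a
#'   second methylation timepoint (persistence stage; default 2).
#' @param alpha Meta-analysis significance threshold (default 1e-7).
#' @param region_window Region-pruning window in bp (default 1e6).
#' @param clump_window,clump_r2,instrument_p Clumping window (bp), LD
#'   r-squared threshold, and instrument p-value threshold.
#' @param fdr_alpha FDR level for the MR scan (default 0.05).
#' @param mediation_draws Quasi-Bayesian draw count (default 2000).
#' @param mediation_cpg CpG used as the mediator (default: the first
#'   CpG with a configured causal effect on the outcome).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_cohorts = 5,
                            cohort_dirs = NULL,
                            sim = list(),
                            covariates = c("sex", "bmi", "own_smoking",
                                           "social_class"),
                            technical_covariates = NULL,
                            n_timepoint2_cohorts = 2,
                            alpha = 1e-7,
                            region_window = 1e6,
                            clump_window = 1e6,
                            clump_r2 = 0.001,
                            instrument_p = 1e-7,
                            fdr_alpha = 0.05,
                            mediation_draws = 2000,
                            mediation_cpg = NULL) {
  assert_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  assert_scalar_number(region_window, "region_window", 0, Inf,
                       strict_lower = TRUE)
  assert_scalar_number(clump_window, "clump_window", 0, Inf,
                       strict_lower = TRUE)
  assert_scalar_number(clump_r2, "clump_r2", 0, 1)
  assert_scalar_number(instrument_p, "instrument_p", 0, 1,
                       strict_lower = TRUE)
  assert_scalar_number(fdr_alpha, "fdr_alpha", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  mediation_draws <- assert_count(mediation_draws, "mediation_draws", 100L)
  n_cohorts <- assert_count(n_cohorts, "n_cohorts")
  n_timepoint2_cohorts <- assert_count(n_timepoint2_cohorts,
                                       "n_timepoint2_cohorts", 0L)
  seed <- assert_count(seed, "seed", 0L)
  if (!is.null(cohort_dirs)) {
    missing <- cohort_dirs[!dir.exists(cohort_dirs)]
    if (length(missing) > 0L) {
      abort(sprintf("cohort director%s not found: %s.",
                    if (length(missing) > 1L) "ies" else "y",
                    paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(out_dir = out_dir, seed = seed, n_cohorts = n_cohorts,
         cohort_dirs = cohort_dirs, sim = sim, covariates = covariates,
         technical_covariates = technical_covariates,
         n_timepoint2_cohorts = n_timepoint2_cohorts,
         alpha = alpha, region_window = region_window,
         clump_window = clump_window, clump_r2 = clump_r2,
         instrument_p = instrument_p, fdr_alpha = fdr_alpha,
         mediation_draws = mediation_draws, mediation_cpg = mediation_cpg),
    class = "pipeline_config"
  )
}

# Technical PCs plus all but one cell proportion (they sum to one, so
# the full set is collinear with an intercept).
default_technical_covariates <- function(covariates) {
  tpc <- grep("^tpc_", names(covariates), value = TRUE)
  cell <- grep("^cell_prop_", names(covariates), value = TRUE)
  c(tpc, head(cell, -1L))
}

#' Run the full analytic chain end to end
#'
#' Executes simulate (or load) -> per-cohort EWAS and variants ->
#' inverse-variance weighted meta-analysis -> threshold + region
#' pruning -> two-timepoint persistence (when a second timepoint
#' exists) -> Mendelian randomization -> mediation, writing each
#' stage's TSV under `config$out_dir`, a log of seeds and row counts,
#' and a manifest of output hashes. Any stage failure halts the run
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage outputs and the paths of
#'   the files written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(config$seed, config$n_cohorts + 3L)
  log_lines <- c(sprintf("methlink pipeline, master seed %d", config$seed),
                 sprintf("package version %s",
                         as.character(utils::packageVersion("methlink"))))
  paths <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- simulate / load ------------------------------------------------
  results <- list()
  bundles <- list()
  bundles_t2 <- list()
  truths <- list()
  sim_dir <- file.path(out, "simulate")
  if (is.null(config$cohort_dirs)) {
    stage("simulate", {
      for (i in seq_len(config$n_cohorts)) {
        args <- config$sim
        args$seed <- seeds[i]
        cfg <- do.call(sim_config, args)
        sim <- simulate_cohort(cfg)
        bundles[[i]] <- sim$bundle
        truths[[i]] <- sim$truth
        cdir <- file.path(sim_dir, sprintf("cohort_%d", i))
        write_cohort_bundle(sim$bundle, cdir)
        write_truth(sim$truth, file.path(cdir, "truth.yaml"))
        paths <- c(paths, file.path(cdir, "t1_methylation.tsv"))
        if (i <= config$n_timepoint2_cohorts) {
          b2 <- simulate_second_timepoint(sim$bundle, cfg)
          bundles_t2[[i]] <- b2
          write_cohort_bundle(b2, cdir)
        }
      }
    })
  } else {
    stage("load", {
      for (i in seq_along(config$cohort_dirs)) {
        bundles[[i]] <- read_cohort_bundle(config$cohort_dirs[i])
        t2 <- file.path(config$cohort_dirs[i], "t2_methylation.tsv")
        if (file.exists(t2)) {
          bundles_t2[[i]] <- read_cohort_bundle(config$cohort_dirs[i],
                                                 prefix = "t2")
        }
      }
    })
  }
  log_lines <- c(log_lines, sprintf("cohorts: %d", length(bundles)))

  # --- ewas -----------------------------------------------------------
  ewas_dir <- file.path(out, "ewas")
  dir.create(ewas_dir, showWarnings = FALSE)
  per_cohort <- stage("ewas", {
    purrr::imap(bundles, function(b, i) {
      main <- fit_ewas(b, "maternal_smoking", config$covariates)
      never <- fit_ewas(restrict_never_smokers(b), "maternal_smoking",
                        setdiff(config$covariates, "own_smoking"),
                        model_tag = "never_smokers")
      dose <- fit_dose_response(b, config$covariates)
      negctl <- fit_negative_control(b, config$covariates)
      all <- dplyr::bind_rows(main, never, dose, negctl)
      p <- file.path(ewas_dir, sprintf("cohort_%d_ewas.tsv", i))
      write_records(all, p)
      list(main = main, never = never, dose = dose, negctl = negctl)
    })
  })
  paths <- c(paths,
             file.path(ewas_dir, sprintf("cohort_%d_ewas.tsv",
                                         seq_along(bundles))))
  results$ewas <- per_cohort

  # --- meta -----------------------------------------------------------
  meta <- stage("meta", ivw_meta(purrr::map(per_cohort, "main")))
  meta_path <- file.path(out, "meta.tsv")
  write_records(meta, meta_path)
  paths <- c(paths, meta_path)
  results$meta <- meta

  # --- regions --------------------------------------------------------
  regions <- stage("regions", {
    sig <- apply_threshold(meta, config$alpha)
    sig <- dplyr::left_join(sig, bundles[[1]]$annotation, by = "cpg_id")
    select_leading_cpgs(sig, window = config$region_window)
  })
  regions_path <- file.path(out, "regions.tsv")
  write_records(regions, regions_path)
  paths <- c(paths, regions_path)
  results$regions <- regions

  # --- persistence ----------------------------------------------------
  if (length(bundles_t2) > 0L) {
    persist <- stage("persistence", {
      purrr::imap_dfr(purrr::compact(bundles_t2), function(b2, i) {
        persistence_analysis(
          bundles[[i]], b2,
          technical_covariates = config$technical_covariates %||%
            default_technical_covariates(bundles[[i]]$covariates),
          study_covariates = intersect(config$covariates,
                                       names(bundles[[i]]$covariates))
        ) |>
          dplyr::mutate(cohort = i)
      })
    })
    persist_path <- file.path(out, "persistence.tsv")
    write_records(persist, persist_path)
    paths <- c(paths, persist_path)
    results$persistence <- persist
  }

  # --- mr -------------------------------------------------------------
  args <- config$sim
  if (!is.null(args$n_snps) && args$n_snps > 0L) {
    mr <- stage("mr", {
      args$seed <- seeds[config$n_cohorts + 1L]
      cfg <- do.call(sim_config, args)
      inputs <- simulate_mr_inputs(cfg)
      write_records(inputs$mqtl, file.path(out, "mqtl.tsv"))
      write_records(inputs$gwas, file.path(out, "gwas.tsv"))
      write_ld_matrix(inputs$ld, file.path(out, "ld.tsv"))
      inst <- select_and_clump(inputs$mqtl, inputs$ld,
                               p_threshold = config$instrument_p,
                               window_bp = config$clump_window,
                               r2_threshold = config$clump_r2)
      mr_scan(inst, inputs$gwas, fdr_alpha = config$fdr_alpha)
    })
    mr_path <- file.path(out, "mr.tsv")
    write_records(mr, mr_path)
    paths <- c(paths, mr_path)
    results$mr <- mr
  }

  # --- mediation ------------------------------------------------------
  if ("outcome" %in% names(bundles[[1]]$covariates)) {
    med <- stage("mediation", {
      b <- bundles[[1]]
      cpg <- config$mediation_cpg %||%
        names(config$sim$causal_cpg_effects_on_outcome)[1]
      dat <- dplyr::bind_cols(
        b$covariates,
        tibble::tibble(mediator = b$methylation[, cpg])
      )
      fit <- fit_mediation_models(
        dat, "maternal_smoking", "mediator", "outcome",
        covariates = intersect(config$covariates, names(b$covariates)),
        outcome_model = if (all(b$covariates$outcome %in% c(0, 1)))
          "logistic" else "linear"
      )
      quasi_bayesian_mediate(fit, n_draws = config$mediation_draws,
                             seed = seeds[config$n_cohorts + 2L])
    })
    med_tbl <- tidy.mediation_record(med)
    med_path <- file.path(out, "mediation.tsv")
    write_records(med_tbl, med_path)
    paths <- c(paths, med_path)
    report <- utils::capture.output(print(med))
    writeLines(report, file.path(out, "mediation_report.txt"))
    results$mediation <- med
  }

  # --- manifest + log -------------------------------------------------
  manifest <- tibble::tibble(
    file = unname(vapply(paths,
                         function(p) sub(paste0("^", out, "/?"), "", p),
                         character(1))),
    md5 = unname(tools::md5sum(paths))
  )
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"),
                   progress = FALSE)
  log_lines <- c(
    log_lines,
    sprintf("stage outputs: %d", nrow(manifest)),
    sprintf("meta records: %d; significant: %d; regions: %d",
            nrow(meta), sum(meta$pval < config$alpha), nrow(regions))
  )
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(c(results, list(manifest = manifest, paths = paths)))
}
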