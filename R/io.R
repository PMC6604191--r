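# TSV dialects for every stage. All files are tab-separated with a
# header row, '.' decimal point, and numbers serialized with enough
# digits to round-trip exactly. CRLF line endings are accepted on read.

read_tsv_checked <- function(path, required, what = basename(path)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, required, sprintf("file '%s'", what))
  df
}

#' Write / read a tabular stage output
#'
#' Thin wrappers over [readr::write_tsv()] / [readr::read_tsv()] that
#' enforce the column contract of each stage table. Numeric fields are
#' serialized at full round-trip precision; missing required columns
#' are reported by name; CRLF line endings are accepted and normalized
#' on read.
#'
#' @param records A tibble of stage records.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; readers return a
#'   tibble.
#' @export
write_records <- function(records, path) {
  records <- tibble::as_tibble(records)
  # flatten list-columns (e.g. region members) to semicolon-joined text
  for (cl in names(records)) {
    if (is.list(records[[cl]])) {
      records[[cl]] <- purrr::map_chr(
        records[[cl]], function(v) paste(unlist(v), collapse = ";")
      )
    }
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_ewas_records <- function(path) {
  df <- read_tsv_checked(path, c("cpg_id", "beta", "se", "pval", "n",
                                 "model_tag"))
  assert_no_duplicates(paste(df$cpg_id, df$model_tag), "cpg_id/model_tag")
  df
}

#' @rdname write_records
#' @export
read_meta_records <- function(path) {
  df <- read_tsv_checked(path, c("cpg_id", "beta", "se", "z", "pval",
                                 "k_studies", "direction"))
  assert_no_duplicates(df$cpg_id, "cpg_id")
  df
}

#' @rdname write_records
#' @export
read_regions <- function(path) {
  df <- read_tsv_checked(path, c("region_id", "chromosome", "leading_cpg",
                                 "n_members", "members"))
  df$members <- strsplit(df$members, ";", fixed = TRUE)
  df
}

#' @rdname write_records
#' @param type `"gwas"` or `"mqtl"` (mQTL tables additionally need a
#'   `cpg` column).
#' @export
read_summary_stats <- function(path, type = c("gwas", "mqtl")) {
  type <- match.arg(type)
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval")
  if (type == "mqtl") need <- c(need, "cpg")
  read_tsv_checked(path, need)
}

#' @rdname write_records
#' @export
read_persistence_records <- function(path) {
  read_tsv_checked(path, c("cpg_id", "beta_t1", "se_t1", "beta_t2",
                           "se_t2", "interaction_beta", "interaction_se",
                           "equality_pval"))
}

#' @rdname write_records
#' @export
read_mr_records <- function(path) {
  read_tsv_checked(path, c("cpg_id", "trait_id", "method", "beta", "se",
                           "pval", "fdr_pval", "n_snps"))
}

#' Read / write an LD matrix as a square TSV
#'
#' The file is a square tab-separated matrix with SNP ids as the header
#' and in the first column.
#'
#' @param ld A square correlation matrix with SNP ids in dimnames.
#' @param path File path.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- tibble::as_tibble(ld, rownames = "snp")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv_checked(path, "snp")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$snp
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    abort("LD file is not a square matrix with matching row/column ids.")
  }
  m
}

#' Write / read a cohort bundle as delimited text
#'
#' A bundle is stored as three TSVs: `<prefix>_methylation.tsv` (rows
#' CpGs, first column `cpg_id`, remaining columns sample ids),
#' `<prefix>_annotation.tsv`, and `<prefix>_covariates.tsv`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Directory (created if needed).
#' @param prefix File-name prefix (defaults to the bundle's timepoint).
#' @return `write_cohort_bundle()` returns `dir` invisibly;
#'   `read_cohort_bundle()` returns a `cohort_bundle`.
#' @export
write_cohort_bundle <- function(bundle, dir, prefix = bundle$timepoint) {
  check_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meth <- tibble::as_tibble(t(bundle$methylation), rownames = "cpg_id")
  readr::write_tsv(meth, file.path(dir, paste0(prefix, "_methylation.tsv")),
                   progress = FALSE)
  readr::write_tsv(bundle$annotation,
                   file.path(dir, paste0(prefix, "_annotation.tsv")),
                   progress = FALSE)
  readr::write_tsv(bundle$covariates,
                   file.path(dir, paste0(prefix, "_covariates.tsv")),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_bundle
#' @param timepoint Timepoint label stored on the bundle after reading.
#' @export
read_cohort_bundle <- function(dir, prefix = "t1", timepoint = prefix) {
  meth <- read_tsv_checked(
    file.path(dir, paste0(prefix, "_methylation.tsv")), "cpg_id"
  )
  assert_no_duplicates(meth$cpg_id, "cpg_id")
  m <- t(as.matrix(meth[, -1, drop = FALSE]))
  colnames(m) <- meth$cpg_id
  annotation <- read_tsv_checked(
    file.path(dir, paste0(prefix, "_annotation.tsv")),
    c("cpg_id", "chromosome", "position", "gene")
  )
  annotation$chromosome <- as.character(annotation$chromosome)
  if (any(annotation$position <= 0 |
          annotation$position != round(annotation$position))) {
    abort("annotation positions must be strictly positive integers.")
  }
  covariates <- read_tsv_checked(
    file.path(dir, paste0(prefix, "_covariates.tsv")), "sample_id"
  )
  assert_no_duplicates(covariates$sample_id, "sample_id")
  if (!setequal(rownames(m), covariates$sample_id)) {
    abort("sample sets of methylation matrix and covariate table differ.")
  }
  m <- m[covariates$sample_id, , drop = FALSE]
  cellcols <- grep("^cell_prop_", names(covariates), value = TRUE)
  if (length(cellcols) > 0L) {
    sums <- rowSums(covariates[, cellcols, drop = FALSE])
    if (any(abs(sums - 1) > 1e-8) ||
        any(covariates[, cellcols] < 0)) {
      abort("cell proportions must be nonnegative and sum to 1 (tol 1e-8).")
    }
  }
  structure(
    list(methylation = m, annotation = annotation,
         covariates = covariates, timepoint = timepoint,
         internals = NULL),
    class = "cohort_bundle"
  )
}

#' Write / read a ground-truth record as structured key-value text
#'
#' @param truth A `truth_record` from [simulate_cohort()].
#' @param path File path (YAML).
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "truth_record")) {
    abort("`truth` must be a truth_record.")
  }
  obj <- list(
    cpg = lapply(seq_len(nrow(truth$cpg)), function(i) as.list(truth$cpg[i, ])),
    mean_cigs_exposed = truth$mean_cigs_exposed,
    mediation = truth$mediation,
    seed = truth$seed
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(
    list(
      cpg = dplyr::bind_rows(lapply(obj$cpg, tibble::as_tibble)),
      mean_cigs_exposed = obj$mean_cigs_exposed,
      mediation = obj$mediation,
      seed = obj$seed
    ),
    class = "truth_record"
  )
}

#' Bundled reference association results for prenatally exposed CpGs
#'
#' `top_cpg_associations()` returns published meta-analysis summary
#' statistics (effect in beta-value units, standard error, p-value,
#' chromosome and 1-based position) for 69 CpG sites differentially
#' methylated in the blood of adolescents and adults prenatally exposed
#' to maternal smoking, pooled over five birth cohorts (N = 2821) by
#' inverse-variance weighted fixed-effects meta-analysis.
#' `leading_cpg_sites()` returns the 36 CpGs selected as region
#' representatives for sensitivity and downstream analyses in that
#' analysis.
#'
#' @return A tibble.
#' @export
top_cpg_associations <- function() {
  read_tsv_checked(
    system.file("extdata", "prenatal_smoking_meta_cpgs.tsv",
                package = "methlink", mustWork = TRUE),
    c("cpg_id", "chromosome", "position", "gene", "beta", "se", "pval")
  ) |>
    dplyr::mutate(chromosome = as.character(.data$chromosome))
}

#' @rdname top_cpg_associations
#' @export
leading_cpg_sites <- function() {
  read_tsv_checked(
    system.file("extdata", "prenatal_smoking_leading_cpgs.tsv",
                package = "methlink", mustWork = TRUE),
    c("cpg_id", "chromosome", "gene")
  ) |>
    dplyr::mutate(chromosome = as.character(.data$chromosome))
}
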