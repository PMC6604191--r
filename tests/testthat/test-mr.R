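mk_mqtl <- function(snp, cpg, beta, se, pval, chr = "1", pos = 1e6,
                    ea = "A", oa = "G", eaf = 0.3) {
  tibble::tibble(snp = snp, chr = chr, pos = pos, effect_allele = ea,
                 other_allele = oa, eaf = eaf, beta = beta, se = se,
                 pval = pval, cpg = cpg)
}

test_that("clumping keeps the strongest SNP and logs LD exclusions", {
  mq <- mk_mqtl(c("rs1", "rs2"), "cpg_1", c(0.2, 0.15), c(0.01, 0.01),
                c(1e-9, 1e-8), pos = c(1e6, 1.2e6))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  inst <- select_and_clump(mq, ld)
  expect_equal(inst$n_snps, 1L)
  expect_equal(inst$snps[[1]]$snp, "rs1")
  expect_equal(inst$exclusions[[1]]$reason, "ld")
  expect_equal(inst$exclusions[[1]]$snp, "rs2")

  # a lone sub-threshold SNP is retained
  one <- select_and_clump(mk_mqtl("rs1", "cpg_1", 0.2, 0.01, 1e-9),
                          ld[1, 1, drop = FALSE])
  expect_equal(one$snps[[1]]$snp, "rs1")

  # above-threshold candidates never become instruments
  none <- select_and_clump(mk_mqtl("rs1", "cpg_1", 0.2, 0.01, 1e-6),
                           ld[1, 1, drop = FALSE])
  expect_equal(nrow(none), 0)

  # SNP absent from LD matrix reported
  expect_error(
    select_and_clump(mk_mqtl("rs9", "cpg_1", 0.2, 0.01, 1e-9), ld),
    "rs9"
  )

  # distant SNPs escape LD clumping
  far <- mk_mqtl(c("rs1", "rs2"), "cpg_1", c(0.2, 0.15), c(0.01, 0.01),
                 c(1e-9, 1e-8), pos = c(1e6, 3e6))
  expect_equal(select_and_clump(far, ld)$n_snps, 2L)
})

test_that("greedy clumping matches the exhaustive oracle on small instances", {
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    snps <- paste0("rs", 1:k)
    mq <- mk_mqtl(snps, "cpg_1",
                  beta = rnorm(k, 0.2, 0.05), se = rep(0.01, k),
                  pval = 10^runif(k, -12, -5),
                  chr = as.character(sample(1:2, k, replace = TRUE)),
                  pos = sample.int(3e6, k))
    L <- matrix(runif(k * k, -0.8, 0.8), k)
    ld <- crossprod(L) / sqrt(outer(diag(crossprod(L)),
                                    diag(crossprod(L))))
    dimnames(ld) <- list(snps, snps)
    got <- select_and_clump(mq, ld, p_threshold = 1e-6,
                            window_bp = 1e6, r2_threshold = 0.1)
    got_snps <- if (nrow(got)) sort(got$snps[[1]]$snp) else character()
    want <- sort(clump_oracle(mq, ld, 1e-6, 1e6, 0.1))
    expect_identical(got_snps, want)
  }
})

test_that("defaults equal the published instrument-selection parameters", {
  expect_identical(formals(select_and_clump)$p_threshold, 1e-7)
  expect_identical(formals(select_and_clump)$window_bp, 1e6)
  expect_identical(formals(select_and_clump)$r2_threshold, 0.001)
})

mk_ss <- function(snp = "rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.2,
                  se = 0.02, pval = 1e-9) {
  tibble::tibble(snp = snp, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pval = pval)
}

test_that("harmonization aligns, flips, and excludes correctly", {
  exp <- mk_ss()
  # identical orientation: untouched
  h <- harmonize(exp, mk_ss(beta = 0.3))
  expect_equal(h$harmonized$beta_out, 0.3)
  expect_equal(nrow(h$exclusions), 0)
  # swapped alleles: sign flip and eaf complement
  h2 <- harmonize(exp, mk_ss(ea = "G", oa = "A", beta = 0.3, eaf = 0.7))
  expect_equal(h2$harmonized$beta_out, -0.3)
  expect_equal(h2$harmonized$eaf_out, 0.3)
  # strand flip: relabeled without sign change
  h3 <- harmonize(exp, mk_ss(ea = "T", oa = "C", beta = 0.3))
  expect_equal(h3$harmonized$beta_out, 0.3)
  # ambiguous palindrome dropped
  h4 <- harmonize(mk_ss(ea = "A", oa = "T", eaf = 0.50),
                  mk_ss(ea = "A", oa = "T", eaf = 0.50))
  expect_equal(nrow(h4$harmonized), 0)
  expect_equal(h4$exclusions$reason, "palindromic-ambiguous")
  # unambiguous palindrome oriented by frequency
  h5 <- harmonize(mk_ss(ea = "A", oa = "T", eaf = 0.10),
                  mk_ss(ea = "A", oa = "T", eaf = 0.88, beta = 0.3))
  expect_equal(h5$harmonized$beta_out, -0.3)
  # incompatible allele sets excluded
  h6 <- harmonize(exp, mk_ss(ea = "A", oa = "C"))
  expect_equal(h6$exclusions$reason, "allele-mismatch")
})

test_that("Wald ratio reproduces the hand-computed delta-method example", {
  w <- wald_ratio(0.2, 0.02, 0.05, 0.01)
  expect_equal(w$beta, 0.25, tolerance = 1e-10)
  expect_equal(w$se, 0.05, tolerance = 1e-10)
  wd <- wald_ratio(0.2, 0.02, 0.05, 0.01, se_method = "delta")
  expect_equal(wd$se, sqrt(0.01^2 / 0.2^2 + 0.05^2 * 0.02^2 / 0.2^4),
               tolerance = 1e-10)
  expect_equal(wd$se, 0.055901699, tolerance = 1e-8)
  # unit instrument passthrough
  u <- wald_ratio(1, 0.01, 0.42, 0.07)
  expect_equal(u$beta, 0.42)
  expect_equal(u$se, 0.07)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "zero")
})

test_that("IVW reproduces hand-computed sums and the duplication identity", {
  iv <- ivw_mr(c(0.2, 0.1), c(0.05, 0.03), c(0.01, 0.01))
  expect_equal(iv$beta, 0.26, tolerance = 1e-10)
  expect_equal(iv$se, 1 / sqrt(500), tolerance = 1e-10)
  # two identical instruments: same point estimate, se smaller by sqrt(2)
  w <- wald_ratio(0.2, 0.02, 0.05, 0.01)
  dup <- ivw_mr(c(0.2, 0.2), c(0.05, 0.05), c(0.01, 0.01))
  expect_equal(dup$beta, w$beta, tolerance = 1e-12)
  expect_equal(dup$se, w$se / sqrt(2), tolerance = 1e-12)
  expect_error(ivw_mr(0.2, 0.05, 0.01), "fewer than 2")
})

test_that("IVW equals inverse-variance pooling of first-order Wald ratios", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    b_exp <- runif(k, 0.05, 0.4) * sample(c(-1, 1), k, replace = TRUE)
    b_out <- rnorm(k, 0.1, 0.05)
    se_out <- runif(k, 0.005, 0.05)
    iv <- ivw_mr(b_exp, b_out, se_out)
    wr <- b_out / b_exp
    wse <- se_out / abs(b_exp)
    wgt <- 1 / wse^2
    expect_equal(iv$beta, sum(wr * wgt) / sum(wgt), tolerance = 1e-12)
    expect_equal(iv$se, 1 / sqrt(sum(wgt)), tolerance = 1e-12)
  }
})

test_that("records are invariant to flipping the coded allele of any input", {
  exp <- mk_ss(beta = 0.25, eaf = 0.3)
  out <- mk_ss(beta = 0.08, se = 0.01, eaf = 0.3)
  base <- harmonize(exp, out)$harmonized
  w1 <- wald_ratio(base$beta_exp, base$se_exp, base$beta_out, base$se_out)
  # flip the outcome record's coded allele
  out_fl <- mk_ss(ea = "G", oa = "A", beta = -0.08, se = 0.01, eaf = 0.7)
  fl <- harmonize(exp, out_fl)$harmonized
  w2 <- wald_ratio(fl$beta_exp, fl$se_exp, fl$beta_out, fl$se_out)
  expect_identical(w1, w2)
  # flip the exposure record's coded allele too: same causal estimate
  exp_fl <- mk_ss(ea = "G", oa = "A", beta = -0.25, eaf = 0.7)
  fl2 <- harmonize(exp_fl, out)$harmonized
  w3 <- wald_ratio(fl2$beta_exp, fl2$se_exp, fl2$beta_out, fl2$se_out)
  expect_equal(w3$beta, w1$beta, tolerance = 1e-12)
  expect_equal(w3$se, w1$se, tolerance = 1e-12)
})

test_that("scaling exposure effects by c divides the causal estimate by c", {
  b_exp <- c(0.2, 0.1); b_out <- c(0.05, 0.03); se_out <- c(0.01, 0.01)
  base <- ivw_mr(b_exp, b_out, se_out)
  scaled <- ivw_mr(3 * b_exp, b_out, se_out)
  expect_equal(scaled$beta, base$beta / 3, tolerance = 1e-12)
  wb <- wald_ratio(0.2, 0.02, 0.05, 0.01)
  ws <- wald_ratio(0.4, 0.04, 0.05, 0.01)
  expect_equal(ws$beta, wb$beta / 2, tolerance = 1e-12)
})

test_that("a single estimable pair gets fdr equal to its raw p", {
  mq <- mk_mqtl("rs1", "cpg_1", 0.2, 0.01, 1e-9)
  ld <- matrix(1, dimnames = list("rs1", "rs1"))
  inst <- select_and_clump(mq, ld)
  out <- dplyr::mutate(mk_ss(beta = 0.05, se = 0.01), trait_id = "d1")
  scan <- mr_scan(inst, out)
  expect_equal(scan$fdr_pval, scan$pval)
  expect_equal(scan$method, "wald_ratio")
})

test_that("the sign-consistency filter generalizes the timepoint exclusion", {
  mq <- mk_mqtl(c("rs1", "rs2"), c("cpg_1", "cpg_2"), c(0.2, 0.3),
                c(0.01, 0.01), c(1e-9, 1e-9), pos = c(1e6, 3e6))
  ld <- diag(2); dimnames(ld) <- list(c("rs1", "rs2"), c("rs1", "rs2"))
  inst <- select_and_clump(mq, ld)
  out <- dplyr::bind_rows(
    dplyr::mutate(mk_ss("rs1", beta = 0.05, se = 0.01), trait_id = "d1"),
    dplyr::mutate(mk_ss("rs2", beta = 0.05, se = 0.01), trait_id = "d1")
  )
  other_tp <- mk_mqtl(c("rs1", "rs2"), c("cpg_1", "cpg_2"), c(0.18, -0.25),
                      c(0.01, 0.01), c(1e-8, 1e-8))
  scan <- mr_scan(inst, out, consistency_tables = list(tp2 = other_tp))
  expect_setequal(scan$cpg_id, "cpg_1")  # cpg_2's instrument flipped sign
})

test_that("null MR scans control the false discovery rate", {
  n_seeds <- 100
  n_traits <- 100
  discoveries <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(
      n_cpgs = 5, n_snps = 5,
      mqtl_effects = data.frame(snp = paste0("rs", 1:5),
                                cpg = paste0("cpg_", 1:5),
                                beta = rep(0.2, 5)),
      causal_cpg_effects_on_outcome = numeric(),  # global null
      mqtl_sample_size = 5000, gwas_sample_size = 20000,
      seed = s
    )
    traits <- tibble::tibble(
      trait_id = rep(paste0("trait_", seq_len(n_traits)), each = 5),
      cpg_id = rep(paste0("cpg_", 1:5), n_traits),
      theta = 0
    )
    inp <- simulate_mr_inputs(cfg, trait_effects = traits)
    inst <- select_and_clump(inp$mqtl, inp$ld)
    scan <- mr_scan(inst, inp$gwas)
    sum(scan$significant)
  }, numeric(1))
  expect_gte(mean(discoveries <= 1), 0.95)
})

test_that("planted causal effects are recovered in a trait-by-CpG scan", {
  # 15 instrumented CpGs scanned against many traits, 4 true effects
  n_cpgs <- 15
  n_traits <- 30
  planted <- tibble::tibble(
    trait_id = c("trait_1", "trait_2", "trait_3", "trait_4"),
    cpg_id = c("cpg_1", "cpg_2", "cpg_3", "cpg_4"),
    theta = c(-0.4, 0.35, -0.3, 0.45)
  )
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(
      n_cpgs = n_cpgs, n_snps = n_cpgs,
      mqtl_effects = data.frame(snp = paste0("rs", 1:n_cpgs),
                                cpg = paste0("cpg_", 1:n_cpgs),
                                beta = rep(0.25, n_cpgs)),
      mqtl_sample_size = 5000, gwas_sample_size = 50000,
      seed = 500 + s
    )
    grid <- tidyr::expand_grid(
      trait_id = paste0("trait_", seq_len(n_traits)),
      cpg_id = paste0("cpg_", seq_len(n_cpgs))
    )
    grid <- dplyr::left_join(grid, planted,
                             by = c("trait_id", "cpg_id"))
    grid$theta[is.na(grid$theta)] <- 0
    inp <- simulate_mr_inputs(cfg, trait_effects = grid)
    inst <- select_and_clump(inp$mqtl, inp$ld)
    scan <- mr_scan(inst, inp$gwas)
    found <- dplyr::inner_join(scan[scan$significant, ], planted,
                               by = c("trait_id", "cpg_id"))
    nrow(found) == nrow(planted)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
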