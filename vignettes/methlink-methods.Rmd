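---
title: "Methods: from prenatal smoke exposure to methylation and disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from prenatal smoke exposure to methylation and disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

## The analytic chain

methlink implements the full chain of analyses used to ask whether
maternal smoking during pregnancy alters offspring blood DNA
methylation, whether those alterations persist into adulthood, and
whether they causally mediate later-life disease risk. The chain runs:
per-cohort EWAS (with never-smoker, dose-response, and paternal
negative-control variants) → inverse-variance weighted fixed-effects
meta-analysis → significance thresholding and leading-CpG region
pruning → two-timepoint persistence GLS → two-sample Mendelian
randomization → quasi-Bayesian causal mediation. Each stage is an
exported function operating on plain tibbles, so stages can be run,
inspected, and rerun in isolation; `run_pipeline()` chains them and
writes TSVs with a hash manifest.

## Per-cohort EWAS

For each CpG $j$, the cohort model is ordinary least squares

$$\mathrm{meth}_{ij} = \alpha_j + \beta_j\,\mathrm{exposure}_i +
\gamma_j^\top z_i + \varepsilon_{ij},$$

with methylation analyzed untransformed on the beta-value scale
(fractions in $[0,1]$) — effect sizes are then directly interpretable as
methylation differences, which is how the reference results for the 69
exposed-offspring CpGs are expressed. Two-sided p-values use the $t$
distribution with residual degrees of freedom at the cohort level; at
the meta level the standard normal is used, the conventional choice for
inverse-variance pooling. At cohort sizes of several hundred the two are
numerically indistinguishable; the difference matters only for toy
fixtures.

Complete cases are used per model and zero-variance CpGs are skipped
with a message. Rank-deficient designs abort with the offending columns
named, rather than silently dropping terms — in this pipeline a
collinear covariate is almost always a configuration error (e.g.
supplying all cell-type proportions, which sum to one, alongside an
intercept; supply all but one).

Variants:

* **Never-smokers** (`restrict_never_smokers()`): the subset with
  `own_smoking == 0`, refit without the own-smoking covariate (constant
  in the subset). If offspring's own smoking were driving the exposure
  association, the subset estimates would shrink; concordance between
  full and subset estimates is the sensitivity claim.
* **Dose-response** (`fit_dose_response()`): methylation standardized
  per CpG to zero mean and unit SD, regressed on cigarettes/day over the
  full cohort including unexposed (dose 0) mothers; the per-cigarette
  slope and SE are multiplied by 3, so effects read as SD of methylation
  per three additional cigarettes per day. Including the zero-dose
  mass reflects how the dose variable actually arises (most mothers
  smoke zero cigarettes).
* **Negative control** (`fit_negative_control()`): three fits — maternal
  exposure, paternal exposure, and maternal adjusted for paternal.
  Paternal smoking shares the family's confounding structure but has no
  intrauterine path, so paternal effects of similar magnitude would
  indicate confounding; substantially smaller paternal effects support a
  direct biological effect of in-utero exposure.

## Meta-analysis and region pruning

`ivw_meta()` pools per-study estimates with weights $w_i = 1/se_i^2$:
$\hat\beta = \sum w_i b_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$. CpGs
observed in a subset of studies are pooled over that subset with
`k_studies` recorded; a per-study `+`/`-` direction string supports
quick concordance checks. Cochran's Q is computed and reported but never
gates inclusion — no heterogeneity filter is part of the procedure.

The significance threshold is $P < 1\times10^{-7}$ with *strict*
inequality, approximately a Bonferroni level of 0.05 for 450,000
independent tests — a deliberately conservative choice given the
array-wide context the candidate CpGs came from.

`select_leading_cpgs()` partitions significant CpGs into genomic
regions greedily: the unassigned CpG with the smallest p-value leads a
region and absorbs all unassigned CpGs on its chromosome within
`window/2` (default 500 kb, i.e. a 1-Mb window centered on the leader);
repeat until none remain. Two numerical choices deserve note:

* **Tie-break.** Published tables print p-values to three significant
  digits, so genuinely different association strengths can tie. Since
  the p-value is a monotone function of $|z| = |\beta/se|$, ties are
  broken by descending $|z|$ when effect and SE columns are available,
  then by ascending (chromosome, position). This makes the partition
  deterministic under input permutation and resolves printed-precision
  ties in favor of the stronger signal.
* **Window interpretation.** "1-Mb window centered on the leader" is
  implemented as a ±500 kb radius. On the bundled 69-CpG reference
  table this reproduces the published count of 36 regions exactly, and
  keeps the two *CNTNAP2*-region leaders (813,904 bp apart) distinct.

On that reference table the greedy minimum-P rule recovers 33 of the 36
published region representatives. In three regions (*MYO1G*, *AHRR*,
*FRMD4A*) the published representative is not the smallest-P member of
its region under any tie-break consistent with the printed statistics
(each cluster contains a member with a printed p-value several orders of
magnitude smaller); the package implements the stated rule rather than
special-casing those three choices, and the test suite documents the
difference.

`bh_fdr()` wraps `stats::p.adjust(method = "BH")` with input validation;
it is used both for the MR scan and wherever a step-up adjustment is
needed.

## Persistence across timepoints

The longitudinal question — do exposure-associated methylation
differences change between two adult timepoints? — is answered by a
two-stage procedure:

1. **Residualization** (`residualize()`): per timepoint, methylation is
   regressed on technical covariates (technical PCs, cell-type
   proportions) and the residuals carried forward. The two-stage form is
   retained deliberately even though a one-stage model (technical
   covariates inside the GLS) is statistically cleaner; the one-stage
   variant is available behind `one_stage = TRUE` in
   `persistence_analysis()`.
2. **Stacked GLS** (`fit_gls_persistence()`): residuals from both
   timepoints enter one model with exposure, timepoint, exposure ×
   timepoint, and study covariates. Errors are allowed to be correlated
   within individual and heteroskedastic between timepoints: an
   unstructured 2×2 covariance (two variances, one correlation), which
   is fully general for two timepoints. It is estimated by iterated
   feasible GLS — alternate between GLS given the covariance and
   moment re-estimation of the covariance from residuals — to a relative
   coefficient tolerance of 1e-8 with a cap of 100 iterations
   (non-convergence is warned per CpG and flagged in the output). The
   estimated correlation is clamped to ±0.999 to keep the per-individual
   Cholesky factor well conditioned.

The timepoint-specific effects are $\beta_{t1}$ (exposure coefficient)
and $\beta_{t2} = \beta_{t1} + \beta_{\mathrm{int}}$, and the test of
equal effects at the two timepoints is exactly the Wald test of the
interaction being zero. Individuals observed at a single timepoint are
retained (unbalanced GLS) and enter with a 1×1 error block; the output
records how many individuals were paired, making the handling auditable.
With balanced pairs the design is a saturated reparameterization of two
per-timepoint models, so the GLS point estimates coincide with
per-timepoint OLS for any error covariance — a useful exact oracle that
the tests exploit; the covariance estimation affects standard errors and
the unbalanced case. When two cohorts carry two timepoints, their
per-timepoint coefficients and interaction terms are pooled with
`ivw_meta()` after the per-cohort equality tests, i.e. meta-analysis
operates on the cohort-level coefficients.

## Two-sample Mendelian randomization

Methylation is the exposure, disease the outcome, and mQTLs the
instruments, with SNP→CpG and SNP→disease effects taken from separate
samples:

* **Instrument selection and clumping** (`select_and_clump()`):
  candidate SNPs need mQTL $P < 10^{-7}$; greedy clumping by ascending
  p-value drops a candidate lying within half the 1-Mb window of an
  already-retained SNP *and* in LD at $r^2 \ge 0.001$ with it. All
  exclusions are logged with reasons. The mQTL record type carries
  optional `chr`/`pos` columns because the distance rule needs
  positions; when absent, clumping falls back to LD-only (every pair
  treated as within-window), the conservative direction.
* **Harmonization** (`harmonize()`): outcome records are aligned to the
  exposure's effect allele; swapped alleles flip the sign and complement
  the frequency, strand flips are resolved by complementing, and
  palindromic SNPs (A/T, C/G) with exposure allele frequency in
  [0.42, 0.58] are excluded as strand-ambiguous. Non-ambiguous
  palindromes are oriented by frequency concordance.
* **Estimation**: one instrument → Wald ratio $\beta_{GD}/\beta_{GE}$;
  two or more → fixed-effects IVW,
  $\hat\theta = \sum b_{GE} b_{GD}/se_{GD}^2 \big/ \sum b_{GE}^2/se_{GD}^2$.
  The default Wald SE is first order ($se_{GD}/|b_{GE}|$), the
  convention of standard two-sample MR practice; the full delta-method
  SE (propagating instrument uncertainty) sits behind
  `se_method = "delta"`. Random-effects IVW is deliberately absent —
  with at most a handful of instruments per CpG it is not meaningful.
* **Scan and FDR** (`mr_scan()`): one estimate per (CpG, trait) pair and
  Benjamini–Hochberg across *all* pairs in the scan as one family. An
  optional consistency filter drops instruments whose mQTL effect
  changes sign across supplied timepoint tables, generalizing the
  exclusion of instruments unstable over the life course.

## Quasi-Bayesian mediation

`fit_mediation_models()` fits the mediator model (CpG on exposure and
covariates, OLS) and the outcome model (outcome on exposure, mediator,
and covariates; OLS or ML logistic), storing robust HC3 sandwich
covariances. By convention the *total* effect comes from the
mediator-free outcome model and the *direct* effect from the
mediator-containing one; in the fully linear case total − direct equals
the product of paths $a \cdot b$.

`quasi_bayesian_mediate()` draws `n_draws` (default 2000) coefficient
vectors from the normal approximation around the fits with the robust
covariances and computes, per draw, the average causal mediation effect
(ACME), average direct effect (ADE), and total effect. Linear outcome
models with no exposure–mediator interaction admit the closed form
ACME$_d = a_d b_d$, ADE$_d$ = exposure coefficient, so the identity
ACME + ADE = TE holds to machine precision per draw. Logistic outcomes
are handled on the probability scale: mediator values are simulated
around their predicted means with the mediator-model residual SD (one
error draw per individual, shared between exposure arms as a variance
reduction) and potential-outcome contrasts averaged over individuals and
both exposure arms. Point estimates are means over draws, intervals are
2.5/97.5 percentiles, and p-values are two-sided simulation tails. No
exposure×mediator interaction is included by default.

The **proportion mediated** is summarized as the per-draw *median* of
ACME/TE with a percentile interval: ratios of means are unstable when
the total effect is small, and the median of ratios is robust to the
heavy tails the ratio draws develop. The ratio of mean ACME to mean TE
is also reported for comparison. When the total-effect interval covers
zero — or the ACME and TE point estimates disagree in sign — the ratio
is not interpretable and an instability flag is raised rather than a
silent number.

## The synthetic-data generator

`simulate_cohort()` emulates exactly the structure the downstream
stages assume, with a recorded ground truth for recovery tests:

* Methylation is generated directly on the beta-value scale as
  baseline + exposure effect + dose slope × cigarettes/day + covariate
  loadings + cell-type mixture contribution + Gaussian noise, clipped to
  $[0,1]$. Clipping events are reported; with the default `noise_sd` of
  0.05 and baselines drawn in $[0.2, 0.8]$ they stay well below 0.1% of
  entries. Working on the beta scale (rather than logit/M-values)
  matches the scale on which the pipeline analyzes and reports effects.
* Cigarettes/day among exposed mothers follow a zero-truncated Poisson
  parameterized by its mean (default 3/day) — exposure is defined as at
  least one cigarette per day — and exactly zero otherwise.
* Maternal and paternal smoking arise from a shared latent environment
  (bivariate normal liability, default correlation 0.5, marginal
  prevalences 0.16 and 0.30); paternal smoking has *no* direct effect on
  methylation. This builds the negative-control assumption into the
  generative model, so attenuated paternal estimates are the correct
  answer, not an artifact.
* Cell-type proportions are Dirichlet (neutrophil-dominant for six
  subtypes) with CpG-specific loadings — a stand-in for measured
  leukocyte composition entering as covariates.
* Second timepoints reuse the same individuals; the exposure effect is
  scaled per CpG by `persistence_fractions`, residuals correlate within
  individual across timepoints (default 0.4) and may differ in SD
  (default 1.2× the first timepoint), matching the persistence model's
  error assumptions.
* MR inputs are valid instruments by construction: SNP→outcome effects
  equal the true causal effect times the SNP→CpG effect, with sampling
  error governed by configurable instrument/GWAS sample sizes (infinite
  sizes give error-free summary statistics for exactness tests). The LD
  matrix is AR(1) within chromosome — positive semidefinite with unit
  diagonal — not a realistic block structure.
* Outcomes follow the mediation path structure: continuous traits by a
  linear model, binary disease by a liability threshold at the
  configured prevalence.

Default magnitudes were chosen once so that exposure effects in the
0.005–0.08 beta-unit range of the reference results are detectable when
about five cohorts of ~560 samples are pooled (residual SD 0.05 gives a
pooled SE of ~0.003, comparable to the published SEs at N = 2821); the
reference analysis does not state per-CpG methylation variances, so
these are the package's own calibration, not published values.

What the generator does *not* emulate — array intensities, probe-type
and batch artifacts, normalization pipelines, realistic LD blocks,
genetic confounding of exposure — bounds what passing tests show:
the statistical machinery recovers known truths under its stated
assumptions; it says nothing about raw-array preprocessing, which enters
this pipeline only as pre-computed covariates.

## Problem sizes and reproducibility

Deterministic behavior is a contract: every stochastic function takes a
seed, the pipeline spawns per-stage seeds from one master seed, and
reruns are byte-identical (hash manifest). The test suite exercises the
chain at sizes chosen to make Monte-Carlo bands tight without excess
runtime: EWAS calibration on 5000 null CpGs at n = 400; persistence
calibration over 200 replicates at 2000 individuals; mediation recovery
at n = 5000 with 2000 draws and interval coverage over 200 replicates at
n = 2000; MR coverage over 200 seeds. Recovery assertions use
Monte-Carlo standard errors (3×) rather than fixed slacks wherever a
quantity is estimated by simulation.

## Known limitations

* Per-CpG GLS is looped in R; for two timepoints and tens of thousands
  of CpGs it remains tractable, but no attempt is made at the
  array-scale optimizations a production EWAS engine would use.
* The MR module implements Wald/IVW only — no pleiotropy-robust
  estimators (MR-Egger, weighted median) and no colocalization; with one
  or two instruments per CpG those are not identified anyway.
* The FDR family for the MR scan is all pairs in one scan; published
  FDR columns computed under other (unstated) family definitions will
  not reproduce exactly from printed raw p-values.
* Sequential-ignorability sensitivity analysis for mediation and
  multiple joint mediators are out of scope.
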