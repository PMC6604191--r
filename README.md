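# methlink

Maternal smoking during pregnancy leaves a methylation signature in the
blood of exposed offspring that is detectable decades later. **methlink**
implements, as a tested and reusable R pipeline, the full analytic chain
that links that prenatal exposure to offspring blood DNA methylation and
onward to later-life disease:

1. **Per-cohort EWAS** — for each CpG site, ordinary least squares of the
   methylation beta value on sustained maternal smoking plus study
   covariates, with three sensitivity variants: a never-smoker subset
   (excluding offspring who ever smoked regularly), a dose-response model
   (SD units of methylation per three additional cigarettes/day), and a
   paternal-smoking negative control (paternal smoking shares the
   confounding structure of maternal smoking but has no intrauterine
   path, so similar effect sizes would indicate confounding).
2. **Meta-analysis and region pruning** — inverse-variance weighted
   fixed-effects pooling across cohorts (weights `1/se²`, pooled
   `se = (Σw)^(-1/2)`), significance at `P < 1×10⁻⁷`, and greedy
   leading-CpG selection: the smallest-P unassigned CpG leads a region
   and absorbs all CpGs within ±500 kb on its chromosome (a 1-Mb window).
3. **Persistence** — a two-timepoint generalized least squares model of
   residualized methylation on exposure, timepoint, and their
   interaction, with an unstructured 2×2 within-individual error
   covariance estimated by iterated feasible GLS; the test of equal
   effects at the two timepoints is the test of the interaction term.
4. **Two-sample Mendelian randomization** — mQTL instruments selected at
   `P < 10⁻⁷`, clumped (1-Mb window, `r² < 0.001`), harmonized to a
   common effect allele (ambiguous palindromic SNPs excluded), and
   combined by the Wald ratio (`β_GD / β_GE`, one instrument) or the
   inverse-variance weighted estimator (two or more).
5. **Quasi-Bayesian mediation** — coefficient vectors drawn from the
   normal approximation around the fitted mediator and outcome models
   (robust covariance, 2000 draws by default) give the average causal
   mediation effect (ACME), average direct effect (ADE), total effect,
   and the proportion mediated (per-draw median of ACME/TE).

A synthetic-cohort generator (`sim_config()`, `simulate_cohort()`,
`simulate_second_timepoint()`, `simulate_mr_inputs()`) emulates all of
the required inputs — dose-dependent planted effects, a
shared-environment paternal path with no biological effect, two-timepoint
persistence, SNP instruments, and outcomes with a known mediated
fraction — and records the ground truth, so every stage is covered by
parameter-recovery tests.

The package ships the published association results for the 69
prenatal-smoking CpGs (effect sizes, standard errors, P values,
coordinates) and the 36 region-leading CpGs as reference data
(`top_cpg_associations()`, `leading_cpg_sites()`).

## Worked example

```r
library(methlink)

top <- top_cpg_associations()          # 69 CpGs, five cohorts, N = 2821
regions <- select_leading_cpgs(top, window = 1e6)
nrow(regions)
#> [1] 36
dplyr::slice_max(regions, n_members, n = 1)
#> # A tibble: 1 × 6
#>   region_id  chromosome leading_cpg n_members members   window_halfwidth
#>   <chr>      <chr>      <chr>           <int> <list>               <dbl>
#> 1 region_002 15         cg05549655          8 <chr [8]>           500000
```

The 69 published CpGs collapse into 36 genomic regions; the largest is
the eight-CpG *CYP1A1* cluster on chromosome 15 led by cg05549655.

Synthetic end-to-end run with a planted truth:

```r
sim <- list(n_samples = 560, n_cpgs = 100,
            effect_sizes = c(cpg_1 = 0.05, cpg_2 = 0.02),
            causal_cpg_effects_on_outcome = c(cpg_1 = 8),
            direct_exposure_effect_on_outcome = 0.6)
cfg <- pipeline_config(out_dir = "run", seed = 1, n_cohorts = 5,
                       sim = sim)
res <- run_pipeline(cfg)
res$mediation
#> <mediation_record> linear outcome, 2000 draws, n = 560
#>   ACME :   0.3405 [  0.2361,   0.4608]  p = 0
#>   ADE  :   0.6079 [  0.4023,   0.8061]  p = 0
#>   Total:   0.9484 [  0.7341,   1.1501]  p = 0
#>   Proportion mediated: 0.358 [0.252, 0.495]
```

The planted truth here is ACME = 8 × 0.05 = 0.40, direct effect 0.60,
total effect 1.00, proportion mediated 0.40; the single-cohort
(n = 560) estimates above recover each within their intervals.

Each stage writes a TSV under `run/` (per-cohort EWAS records, pooled
meta records, regions, persistence records, MR records, mediation
summary) together with a manifest of output hashes; reruns with the same
seed are byte-identical.

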