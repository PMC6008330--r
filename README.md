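# methmediate

Does DNA methylation *mediate* the effect of a genetic risk locus on a
binary disease phenotype — or is the methylation change a *consequence* of
disease, or an unrelated side effect of the same haplotype? This package
implements the full integrative decision pipeline for that question in
blood methylation data, aimed at statistical geneticists and epigenetics
researchers working with array methylation, genotype dosages and
case-control phenotypes.

For a genotype G, regional methylation M and phenotype Y the package
chains:

1. **Region building** — probe clustering by genomic gap / island
   annotation and collapsed-CpG averaging (`cluster_probes()`,
   `collapse_regions()`), plus reference-based cell deconvolution by
   constrained least squares with PC covariates
   (`estimate_cell_fractions()`, `cell_fraction_pcs()`).
2. **DMR discovery** — bump hunting: covariate-adjusted per-probe
   coefficients of case status, candidate runs above a quantile cutoff,
   and family-wise error control by label permutation of the maximum
   region area, `FWER = (1 + #{max null area ≥ observed})/(B + 1)`
   (`probe_coefficients()`, `find_candidate_regions()`, `dmr_fwer()`).
3. **QTL and association scans** — additive/dominant/recessive dosage
   models with Bonferroni control `α/(n_regions × n_variants)` (for
   7 × 594,262 tests at α = 0.05: 1.20 × 10⁻⁸), logistic
   likelihood-ratio case-control scans with Westfall–Young maxT
   permutation adjustment, conditional scans on an HLA-style design,
   genomic control, and fixed/random-effects meta-analysis
   (`qtl_scan()`, `logistic_assoc_scan()`, `maxt_adjust()`,
   `conditional_scan()`, `genomic_control()`, `meta_analyze()`).
4. **Causal Inference Test** — a logistic CIT whose omnibus p-value is
   the maximum of four component tests (variant–disease,
   variant–methylation given disease, methylation–disease given variant,
   and a residual-permutation equivalence test of G ⫫ Y | M), run in both
   causal directions to call each triplet *mediation*, *consequential*,
   *ambiguous* or *independent* (`cit_classify()`).
5. **Two-sample Mendelian randomization** — LD clumping, allele
   harmonization (palindromic variants dropped), positive orientation of
   exposure effects, and MR-Egger by generalized least squares with error
   covariance `Ω = diag(se_out)·R·diag(se_out)` over the LD matrix R:
   `θ̂ = (XᵀΩ⁻¹X)⁻¹XᵀΩ⁻¹β_out`, with Cochran's Q, the pleiotropy
   intercept test, Steiger directionality
   `Z = (z_exp − z_out)/√(1/(n_exp−3) + 1/(n_out−3))` and a
   measurement-error reliability ratio (`ld_clump()`, `harmonize()`,
   `mr_egger_correlated()`, `steiger_direction()`,
   `steiger_reliability()`).

A synthetic-cohort module (`sim_cohort()`, `sim_genotypes()`,
`sim_methylation()`, `sim_phenotype()`, `sim_expression()`,
`sim_two_sample()`) generates data with known causal structure — block-LD
haplotypes, cell-mixture confounded methylation on the logit scale,
mediation / reverse-causation / pleiotropy phenotypes — and
`run_mediation_pipeline()` drives every stage end to end with a manifest
of seeds and filter counts. The methods vignette
(`vignettes/methylation-mediation.Rmd`) documents the models, parameter
defaults and design choices.

## Worked example

Simulate a 500-sample cohort in which a risk variant hypomethylates an
8-probe region and the methylation change carries the disease risk
(`effect_profile = "strong"` mirrors a major HLA-class-II-like effect),
then classify the planted triplet and run the whole pipeline:

```r
library(methmediate)
cohort <- sim_cohort("mediation", n_samples = 500, seed = 42,
                     effect_profile = "strong")

g <- cohort$geno$dosages[, "rs_drv"]
m <- rowMeans(cohort$meth$betas[, cohort$truth$planted_dmr])
cit_classify(g, m, cohort$pheno$status, n_perm = 1000, seed = 1,
             variant_id = "rs_drv", region_id = "DMR4")
#> <cit_result> rs_drv x DMR4
#>   causal   (G->M->Y): p1 5.49e-13, p2 4.82e-30, p3 1.13e-17, p4 0.000999 -> omnibus 0.000999
#>   reactive (G->Y->M): p1 7.76e-41, p2 0.0974, p3 3.07e-17, p4 0.000999 -> omnibus 0.0974
#>   call: mediation (alpha 0.05)
```

All four causal-direction components are individually significant, so the
omnibus (their maximum) is too; in the reactive direction the
variant–disease link survives adjustment for methylation-as-outcome
(p2 = 0.097 ≥ 0.05), so reverse causation is not supported and the triplet
is called **mediation**.

```r
cfg <- pipeline_config(scenario = "mediation", n_samples = 500, seed = 42,
                       effect_profile = "strong", n_resamples = 200,
                       n_perm_maxt = 200, n_perm_cit = 200)
res <- run_mediation_pipeline(cfg)
#> [methmediate] dmr: 1 candidates, 1 significant at FWER < 0.05
#> [methmediate] meqtl: 6 significant pairs (6 SNPs) at p < 0.00167
#> [methmediate] assoc: 5 SNPs at maxT p < 0.05
#> [methmediate] cit: 5/5 pairs significant; calls: mediation=5
#> [methmediate] mr: egger slope -4.8 (p 4.04e-14), steiger exposure->outcome

res$mr$egger
#> <mr_result> egger, k = 6
#>   slope -4.7997 (SE 0.6349, p 4.04e-14)
#>   intercept -0.0271 (SE 0.0660, p 0.682)
#>   Q 0.964 on 4 df (p 0.915), overdispersion 1.000
```

The filter funnel (1 DMR → 6 meQTL SNPs → 5 associated SNPs → 5
CIT-significant, all called mediation) shrinks monotonically, and the MR
stage recovers the negative causal effect of region methylation on
expression (the generator plants `expr = a − b·m + noise`) with a null
pleiotropy intercept and no heterogeneity.

A command-line wrapper is installed at `inst/cli/methmediate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/methmediate.R", package="methmediate"))')" \
    simulate --scenario mediation --n 500 --seed 42 --out sim_out/
```

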