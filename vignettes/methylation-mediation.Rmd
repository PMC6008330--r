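---
title: "Methods: testing whether DNA methylation mediates genetic disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing whether DNA methylation mediates genetic disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmediate)
```

## The question and the causal triangle

A disease-associated variant G, a methylation signal M at a CpG region, and
a binary phenotype Y can be related in three qualitatively different ways:

* **mediation** (G → M → Y): the variant changes methylation and the
  methylation change carries the disease risk;
* **consequence** (G → Y → M): the variant raises disease risk directly and
  the disease state alters methylation downstream;
* **independence**: G influences M and/or Y through separate paths
  (horizontal pleiotropy), with no causal M–Y link.

`methmediate` implements the full decision pipeline for this question in
blood methylation data: region discovery, QTL screening, case-control
filtering, a Causal Inference Test (CIT) adapted to a binary outcome, and a
two-sample Mendelian randomization (MR) of methylation on expression with
LD-correlated instruments. Every stage can be exercised on synthetic
cohorts whose causal structure is known, which is how the package
demonstrates its operating characteristics.

## Stage 1 — regions instead of single probes

Regulatory methylation changes span runs of neighbouring CpGs, and
averaging across a CpG island or shore suppresses probe-level measurement
error. `cluster_probes()` groups probes whose genomic gap is at most
`max_gap_bp` (default 500 bp, the conventional clustering radius for
450K-style arrays), optionally splitting where the island annotation
changes; `collapse_regions()` averages member probes per sample.
Coordinates are 1-based inclusive internally; BED exports convert to
0-based half-open. The collapsed value is the arithmetic **mean** of
member betas — a median would be more outlier-robust, but the mean keeps
the collapsed value linear in the underlying probes, which the downstream
linear models assume.

## Stage 2 — cell composition as a confounder

Bulk blood methylation mixes six major cell types whose proportions differ
between cases and controls, which can forge or mask case-control
differences. `estimate_cell_fractions()` performs reference-based
deconvolution: per sample, a non-negative least-squares fit of the
observed betas on cell-type reference signatures (solved by the
Lawson–Hanson active-set algorithm via `pracma::lsqnonneg`). The unit-sum
constraint, when requested, is imposed by augmenting the system with a
heavily weighted (1e4) sum row rather than rescaling the solution
afterwards, so an absent cell type does not distort the other fractions;
the returned rows sum to one within 1e-8. `cell_fraction_pcs()` supplies
the first components of the centered fraction matrix as covariates — the
first two PCs capture nearly all compositional variation among six types
and avoid collinearity with the intercept that the raw fractions would
introduce.

## Stage 3 — bump-hunting DMRs with permutation FWER

`probe_coefficients()` fits, per probe, the least-squares coefficient of
case status adjusted for covariates (age, sex, smoking, batch, cell-PCs),
computed through the Frisch–Waugh identity so the whole array is one
matrix product — this is what makes 1,000 label permutations cheap.
Candidate regions are maximal within-cluster runs of at least `min_probes`
(default 2) consecutive probes whose coefficients all exceed the
`cutoff_quantile` (default 0.975) quantile of |coefficient|, with a
consistent sign; a region's *value* is its mean coefficient and its *area*
the sum of |coefficients|. Family-wise error control permutes the
case/control labels (covariates stay attached to samples — exact
exchangeability under the case-control null, in contrast to residual
bootstrap schemes), recomputes the maximum null area at the *same* cutoff,
and assigns each region the add-one estimate
`(1 + #{max null area ≥ observed}) / (B + 1)`. Smoothing
(`smooth_coefficients()`) is available but off by default: with collapsed
island clusters the per-probe coefficients are already regionally
coherent.

One geometric constraint matters when planting signal in simulations: the
fraction of truly affected probes must stay below `1 - cutoff_quantile`,
otherwise the empirical cutoff lands *inside* the affected run and
truncates it. The default synthetic layout therefore uses 400 probes with
an 8-probe planted region (2% < 2.5%).

## Stage 4 — QTL scans and the association funnel

`qtl_scan()` fits `outcome ~ coded dosage + covariates` per variant and
region (additive, dominant or recessive coding; carrier thresholds at
dosage 0.5/1.5, i.e. nearest-genotype rounding of imputed dosages), with
the meQTL family controlled by `bonferroni_threshold(alpha, n_regions,
n_variants)` — for 7 regions × 594,262 variants at α = 0.05 this is
1.20 × 10⁻⁸. Case-control association uses a likelihood-ratio test per
variant (`logistic_assoc_scan()`; LRT rather than Wald for better
small-sample behaviour, Wald SEs still reported) and multiplicity is
handled by Westfall–Young maxT permutation (`maxt_adjust()`): each
variant's statistic is compared to the permutation distribution of the
*maximum* statistic, which adapts to the LD correlation among tests.
Complete separation is flagged; the LRT p-value (still defined through
deviances) is retained and the Wald SE set to NA. `conditional_scan()`
re-runs the logistic scan with a user-supplied condition design —
`hla_condition_design()` builds the presence / homozygote / interaction
indicator columns from an allele-dosage table — and
`genomic_control()` divides χ² statistics by `max(λ, 1)` (deflation is
never "corrected"). `meta_analyze()` provides inverse-variance fixed
effects and DerSimonian–Laird random effects with Cochran's Q, τ² and I².

## Stage 5 — the logistic CIT

For each surviving (variant, region) pair the CIT asks whether the data
are consistent with full mediation. In the causal direction (mediator M,
outcome Y) the four components are

1. `p1`: LRT of G in logistic `Y ~ covariates + G` — the variant is
   associated with disease;
2. `p2`: partial F of G in linear `M ~ covariates + Y + G` — the variant
   is associated with methylation given disease;
3. `p3`: LRT of M in logistic `Y ~ covariates + G + M` — methylation
   carries information about disease beyond the variant;
4. `p4`: a permutation *equivalence* test of G ⫫ Y | M.

The omnibus p-value is the **maximum** of the four: the mediation claim is
supported only if every link is individually demonstrated, which makes the
test conservative by construction under pleiotropy.

The fourth component deserves detail because the published logistic CIT
does not print its permutation scheme; the construction here is a
reconstruction, chosen for three properties and documented as such. The
observed statistic is the LRT of G in `Y ~ covariates + M + G`. Null
mediators are built by fitting `M ~ covariates + G` and adding *permuted
residuals* back to the fitted values: this preserves the G–M association
(required by the equivalence-test logic — the null hypothesis is "no
mediation *despite* a real G–M link") while destroying any M–Y
association beyond G. `p4 = (1 + #{T* ≤ T_obs}) / (B + 1)` is small when
the observed conditional G effect is *smaller* than the null predicts,
i.e. when adjusting for the real M absorbs the G–Y association — exactly
the mediation signature. Ties count toward the null. In the reactive
direction (outcome M, linear models; mediator Y) the same logic applies
with one change: the null permutes Y within strata of the rounded dosage,
which preserves the G–Y association by exact conditional exchangeability
of a discrete G. `cit_classify()` runs both directions and calls
*mediation*, *consequential*, *ambiguous* or *independent* by comparing
the two omnibus p-values to α (default 0.05, 1,000 permutations by
default).

## Stage 6 — two-sample MR with correlated instruments

To test whether region methylation causally drives expression, meQTL
effects (exposure) and eQTL effects (outcome) from two cohorts are
combined. The steps follow standard summary-statistics practice:
greedy LD clumping by p-value (`ld_clump()`, default r² > 0.8 within a
10,000 kb window; ties break by position then id), allele harmonization
(`harmonize()`: outcome betas negated when alleles are swapped, strands
complemented for non-palindromic mismatches, palindromic A/T and C/G
variants dropped outright — no frequency-based rescue), and orientation of
all exposure effects to be positive (`orient_positive()`), which the Egger
intercept requires for interpretability. Because clumping at r² ≤ 0.8
leaves correlated instruments, `mr_egger_correlated()` fits the Egger
regression by generalized least squares with error covariance
`Ω = diag(se_out) · R · diag(se_out)`, where R is the signed LD matrix:
`θ̂ = (XᵀΩ⁻¹X)⁻¹XᵀΩ⁻¹β_out` with design `X = [1, β_exp]`. Heterogeneity is
the GLS residual Q on k−2 df, the coefficient covariance is inflated by
`max(1, Q/df)`, and p-values use the normal reference (the common choice
in correlated-Egger implementations; a t reference would be slightly more
conservative at small k). A near-singular Ω receives a 1e-8 ridge. One
sign convention is fixed and documented: the input LD r is taken as signed
with respect to the *exposure* effect alleles, so outcome-side allele
swaps during harmonization do not touch R, while exposure re-orientation
re-signs the affected rows and columns.

`steiger_direction()` orients causality by comparing variance explained:
per-variant r² is recovered from the t statistic (`r² = t²/(t² + n − 2)`),
Fisher-z transformed, and compared with
`Z = (z_exp − z_out)/√(1/(n_exp−3) + 1/(n_out−3))`.
`steiger_reliability()` asks how robust that inference is to measurement
error: over a 50 × 50 grid of reliabilities in (0.5, 1]², correlations are
disattenuated (`r' = r/√rel`, capped below 1) and the reliability ratio R
is the summed |r'²_exp − r'²_out| over cells favouring the inferred
direction divided by the summed magnitude over cells reversing it. R > 1
supports the inferred direction; when no cell reverses it the ratio is
reported as a finite sentinel (1e6) with an `all_concordant` flag rather
than infinity, keeping downstream tables numeric.

## The synthetic cohort generator

The generator is first-class, tested code; it emulates the *structure* of
a blood methylation mediation study, not any particular dataset.

* **Genotypes** (`sim_genotypes()`): two haplotypes per individual,
  generated block-wise by a first-order copying process in which each
  variant is drawn conditionally on its left neighbour to hit a target
  adjacent-variant correlation r. This gives analytic control of LD at
  desk-scale speed; it produces geometrically decaying within-block LD
  rather than the mosaic patterns of coalescent simulators, which is
  sufficient for exercising clumping, maxT and correlated-Egger code
  paths. The default panel is 30 variants in three blocks (driver block
  and a matched null block at adjacent r = 0.6, plus an LD-free
  background), driver allele frequency 0.5.
* **Methylation** (`sim_methylation()`): per-sample logit-scale signal =
  cell-mixture baseline + planted-region effects, inverse-logit back to
  [0, 1]. The mixture baseline multiplies Dirichlet mixing weights
  (granulocyte-dominated, concentration 60) onto cell-type reference
  profiles, reproducing composition confounding; the planted region adds
  a per-sample biological random effect (`sample_sd`, default 1 logit,
  shared across the region's probes), the genetic effect `g_m × dosage`,
  and probe-level technical noise (`noise_sd`, default 0.1 logit).
  Simulating on the logit scale keeps the [0, 1] support while making
  genetic and confounder effects additive.
* **Phenotype** (`sim_phenotype()`): under mediation,
  `logit P(Y=1) = intercept + m_y · z(m_region)` with the standardized
  collapsed region signal — Y ⫫ G | M holds by construction. Under
  reverse causation, Y is drawn from the genotype first and methylation is
  regenerated with a `y_m · Y` shift. Under independence, Y depends on the
  genotype only (or nothing). The `confounded` scenario leaks the batch
  covariate into both M and Y.
* **Expression** (`sim_expression()`): residualized-expression analogue
  `expr = a − b · m_region + noise` with b > 0, i.e. methylation
  suppresses expression.
* **Two-sample summary statistics** (`sim_two_sample()`): shared true
  exposure effects γ ~ U(0.05, 0.2), outcome effects θγ plus optional
  balanced or directional pleiotropy, sampling noise correlated through
  the LD matrix with SEs scaling as 1/√(2·maf·(1−maf)·n).

**Effect-size calibrations.** The default mediation scenario uses
|g→m| = 0.5 SD of the regional signal per allele and an odds ratio of 2
per SD of methylation at n = 500. This is a *moderate* effect: the implied
marginal variant-disease log-odds is only ≈ 0.33 per allele, whose
single-test power at n = 500 is ≈ 0.6–0.7, and since the CIT omnibus is a
maximum over four components, the mediation call rate at this calibration
is ≈ 0.6 — the package reports it honestly rather than inflating the
generator. A documented `effect_profile = "strong"` preset (1 SD per
allele, OR 3 per SD) mirrors the magnitude of a major HLA-class-II effect
— a roughly 3-fold disease risk with near-complete allelic hypomethylation
— and there the call rate exceeds 0.9. The reverse-causation preset
(variant log-OR 1.0, disease shift −1 SD of methylation, chosen once on
the same major-locus reasoning) yields a consequential call rate ≈ 0.8;
the independence preset is called correctly ≈ 0.97 of the time, and the
causal-direction omnibus rejects in ≈ 2–4% of pleiotropy datasets at
α = 0.05 — conservative, as the max construction predicts.

**What passing tests do and do not show.** The generator has no probe
chemistry artifacts, no detection-p missingness, no realistic
recombination map or population structure, no batch × probe interactions,
and its LD decays geometrically within blocks. Results on it validate the
statistical machinery — calibration under exchangeable nulls, recovery of
planted structure, exactness of closed-form reductions — not robustness
to array-specific artifacts, which real-data preprocessing (normalization,
batch correction) must handle upstream of this package.

## Numerical choices and degenerate inputs

* Add-one permutation estimators everywhere (`(1+x)/(B+1)`): no zero
  p-values, estimates bounded below by 1/(B+1).
* Constant probes: coefficient 0, SE flagged infinite, excluded from the
  bump-hunting cutoff quantile.
* Monomorphic variants: flagged NA effect with p = 1 rather than an error,
  so scans over variant panels never abort.
* Separation in logistic fits (non-convergence or |coef| > 15): flagged;
  LRT p retained, Wald SE set to NA; CIT triplets become `untestable`.
* Clumping ties: p, then position, then id — deterministic output.
* GLS solves go through Cholesky whitening with two triangular solves; a
  failed factorization gets a 1e-8 ridge on the diagonal scale, then
  errors if still singular.
* All generators accept an integer seed and restore the caller's RNG
  state; the pipeline derives per-stage seeds from one master seed and
  records them in its manifest, making re-runs bitwise reproducible.

## Problem sizes used by the test suite

The suite validates operating characteristics at sizes chosen to keep a
full run in single-CPU minutes, stated here as the package's own test
design: CIT type-I on 200 pleiotropy cohorts (150 permutations each),
power/classification on 60–100 cohorts per scenario at n = 500; DMR
recovery on 50 cohorts and null FWER on 200 cohorts at 200 resamples;
Egger coverage on 500 simulated summary-statistics pairs (k = 50
instruments, exposure n = 2 × 10⁵ so that weak-instrument dilution is
negligible — at cohort sizes of a few hundred the Egger slope is visibly
attenuated by exposure sampling noise and *no* estimator attains nominal
coverage); deconvolution on 50 samples × 200 probes × 6 cell types. The
permutation defaults in production use (`n_perm = 1000`,
`n_resamples = 1000`) are scaled down to 120–200 in tests; permutation
p-value granularity changes accordingly but the assertions only involve
rates far from those boundaries.

## Known limitations

* The logistic CIT's p4 is a reconstruction of the cited method's
  behaviour, not a line-by-line port; its calibration is demonstrated by
  simulation, not by equivalence to an external implementation.
* The Egger p-values use a normal reference; at very small k a t
  reference would be more conservative.
* The reliability-ratio integrand is a uniform-grid area ratio; other
  weightings of the reliability plane are conceivable and would change R
  for borderline cases.
* `harmonize()` trusts variant ids; no positional liftover or allele
  frequency comparison is attempted, and palindromic variants are always
  lost.
* The pipeline's MR stage estimates exposure and outcome associations in
  the same simulated cohort generation; a real two-sample design would
  draw them from disjoint cohorts (as `sim_two_sample()` does for the
  estimator-level validation).
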