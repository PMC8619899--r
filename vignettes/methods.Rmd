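---
title: "Methods: GMDR-based interaction detection, polygenic risk scores, and gene-environment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GMDR-based interaction detection, polygenic risk scores, and gene-environment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprs)
```

## Overview

`epiprs` implements a complete case-control statistical-genetics workflow
of the kind used to study gestational diabetes mellitus (GDM) genetics and
its consequences for type 2 diabetes (T2DM) in later life: per-variant
quality control, covariate-adjusted single-SNP association, linkage-
disequilibrium (LD) pruning, exhaustive generalized multifactor
dimensionality reduction (GMDR) to find the best SNP-SNP interaction
model, an unweighted risk-allele polygenic risk score (PRS) over that
model's SNPs, and stratified / interaction-term analysis of PRS-by-
lifestyle effects on a second outcome. Cohort genotype data of this kind
is typically access-restricted, so the package ships a first-class
simulator that reproduces the statistical structure the analysis assumes;
every stage is exercised and tested against synthetic cohorts with known
planted effects.

This vignette records the modelling assumptions, the tunable parameters
and their defaults, the numerical choices, and the design decisions made
where the methodology is genuinely open.

## Data model

Genotypes are held as a subjects-by-variants dosage matrix counting copies
of the **minor** allele (0, 1, 2), with `NA` for missing calls — never a
sentinel value, so no arithmetic can silently absorb missingness.
Positions are 1-based, as in PLINK `.bim` files and VCF. Risk alleles for
the PRS are mapped onto this orientation at scoring time, because a risk
allele may well be the major allele. PLINK bed/bim/fam (SNP-major, magic
bytes `6c 1b 01`) and VCF (GT field) are read and written; the VCF reader
re-orients sites whose ALT allele is the majority allele.

## Quality control

A variant passes QC when, with the default thresholds,

* missing call rate < 4%,
* observed heterozygote fraction < 30%,
* Hardy-Weinberg equilibrium (HWE) p > 0.05.

Each threshold is a config key. Two points deserve comment:

**Heterozygosity.** A "< 30% heterozygosity" rule is ambiguous between a
per-sample and a per-variant reading. The package applies it per variant
(the QC report is variant-level), but note the tension: a variant in
perfect HWE with MAF above ~0.18 has expected heterozygosity 2pq ≥ 0.30
and is excluded by this rule, so under these defaults only relatively
uncommon variants survive. The default simulated cohorts therefore use
MAFs ≤ 0.15. Users analysing common variants should raise `het_rate`.

**HWE method.** The chi-square 1-df goodness-of-fit test is accurate for
large expected counts; for rare genotypes an exact conditional test is
standard. The default `method = "auto"` uses the exact test whenever the
smallest expected genotype count is below 5, chi-square otherwise; both
are available explicitly. The exact p-value is the sum of probabilities of
all heterozygote counts (conditional on the observed allele counts) no
more probable than the observed one.

## Single-SNP association and candidate selection

Association uses an additive (allele-dosage, 1-df trend) logistic
regression with covariates, fitted by IRLS to tolerance 1e-8. The 95% CI
is the Wald interval exp(β ± 1.96·SE). Complete separation is flagged
(infinite CI) rather than raised. Candidates are variants with adjusted
p strictly below 1e-4 (configurable), sorted ascending.

## LD pruning

Pairwise r² between unphased variants is computed from EM-estimated
two-locus haplotype frequencies — the double heterozygote is the only
phase-ambiguous cell — and r² = D²/(p_A q_A p_B q_B). Pruning is a greedy
scan over the p-sorted candidates: a variant is kept iff its r² with every
already-kept variant **on the same chromosome** is at or below 0.3;
cross-chromosome pairs are never tested. Ties in p break by ascending
position. After pruning, the pipeline keeps the top-N by p (default 10) as
a configurable stand-in for any further annotation-based narrowing a study
might apply.

## GMDR

The GMDR score statistic for a binary trait is the residual y − p̂ from
the covariate-only logistic null model; with an intercept the scores sum
to zero, and with no covariates they reduce to 1 − prevalence for cases
and −prevalence for controls.

For a candidate subset of k SNPs, each subject maps to one of 3^k
multilocus genotype cells (subjects missing any subset genotype are
excluded). A cell is labeled **high-risk** iff the sum of training score
residuals in it exceeds the threshold T = 0; empty cells, cells whose sum
is exactly 0, and test cells unseen in training are labeled low-risk —
deterministic and conservative. Subjects are predicted case iff their cell
is high-risk, and performance is balanced accuracy,
(sensitivity + specificity)/2, against the true outcome.

The search is exhaustive over all size-k subsets inside a seeded,
case/control-stratified 10-fold cross-validation (stratification matters:
at ~1-3% prevalence unstratified folds can produce single-class test
sets). Per fold, the subset maximizing *training* balanced accuracy wins;
the reported best model of size k is the subset winning the most folds
(cross-validation consistency, CVC), with ties broken by higher mean
testing balanced accuracy (TEBA) and then lexicographic SNP ids. TRBA and
TEBA are the winner's across-fold means. The sign statistic counts folds
whose testing balanced accuracy is strictly above 0.5 (ties count against
the model) and is referred to the upper Binomial(n_folds, 1/2) tail:

p = Σ_{j ≥ s} C(n, j) / 2^n.

For 10 folds this gives p = 0.828, 0.377, 0.055, 0.011 (0.0107), and
0.001 (0.000977) at s = 4, 6, 8, 9, 10 respectively.

**Selection optimism.** TEBA is honest cross-validation for a *fixed*
subset, but the reported best model is selected — partly via a tie-break
on TEBA itself — from all C(m, k) subsets, so under a null (no genetic
effect) its TEBA sits slightly above 0.5. The effect scales with the
sampling noise of balanced accuracy, i.e. roughly with 1/√(number of
cases): at 10,000 subjects and 3% prevalence (~300 cases, 45 candidate
pairs) the package's null-calibration test measures a mean best-model
TEBA of ~0.53; with more cases it shrinks toward 0.5. Reported TEBA of a
selected model should therefore be read as mildly optimistic, exactly as
with any best-of-many cross-validated selection; CVC and the sign test
are the intended guards.

## Polygenic risk score

The PRS is the unweighted count of risk alleles over the best model's
SNPs: with G the risk allele, genotypes TT/GT/GG score 0/1/2. The risk
allele per SNP is the allele with OR > 1 in the candidate association
(orientation recorded for audit). Default grouping uses fixed cutoffs —
≤ 3 risk alleles Low, 4-5 Medium, ≥ 6 High, natural for a 5-SNP model —
with a tertile mode available; the pipeline falls back to
distribution-based grouping when a small model cannot reach the fixed
cutoffs. Missing genotypes exclude the subject by default
(`missing_policy = "exclude"`); mean imputation is available for
sensitivity analysis and yields a documented non-integer score. No
effect-size weighting is applied anywhere.

Category association is a logistic fit on category dummies with Low as
the reference. Two covariate presets exist in two variants each
(`model1_text`/`model2_text` and `model1_fig`/`model2_fig`), reflecting
the two covariate lists in circulation for this design; both ship and are
selected by config key, with no judgement about which is canonical.

## Gene-environment interaction

Stratified odds ratios fit the same category model independently per
stratum of the lifestyle variable (GDM history, breastfeeding ≥ 1 year,
high/low dietary-pattern intake at the 70th percentile). The interaction
test adds product term(s) between the PRS term and the stratifier to a
joint model: for binary outcomes a likelihood-ratio test of the product
term(s) (Wald optional, numeric PRS only); for continuous outcomes
(fasting glucose, HbA1c) the extra-sum-of-squares F test — a two-way
ANCOVA. Covariate-adjusted group means are least-squares means at the
covariate grand means with Tukey HSD pairwise comparisons (via `emmeans`).
No multiple-testing correction is applied across the lifestyle panel by
default, matching per-test α = 0.05 practice; Bonferroni-style adjustment
can be applied by the user on the returned p-values.

## Dietary patterns

Item intakes aggregate to 29 food groups (the shipped 106-item mapping is
a synthetic default, editable CSV; real studies should substitute their
instrument's mapping). Pattern extraction is PCA on the **correlation**
matrix — intake scales differ by orders of magnitude, so standardization
is required for the eigenvalue rule to be meaningful. Components with
pre-rotation eigenvalue > 1.5 are retained and varimax-rotated with
Kaiser normalization; rotation preserves communalities and the retained
variance. Each component's sign is fixed so its largest-magnitude loading
is positive; groups with |loading| ≥ 0.40 label the pattern. Subject
scores come from the rotated solution by least squares, and high intake
is score ≥ the empirical 70th percentile (linear-interpolation quantile,
type 7; ties fall on the same side, so roughly 30% of subjects are
flagged high). Pure-noise intake matrices retain zero components at
realistic sizes: the largest sample eigenvalue of a 29-variable
correlation matrix at n = 10,000 is about (1 + √(29/10000))² ≈ 1.36 <
1.5. The number of retained components can be fixed a priori via
`n_components`, overriding the eigenvalue rule.

## The cohort simulator

The simulator generates exactly the structure the analysis assumes, so
recovery tests are meaningful:

* **Genotypes**: independent variants from HWE proportions (p², 2pq, q²);
  LD pairs drawn at the haplotype level from two-locus frequencies solved
  from (MAF_A, MAF_B, target r²), with infeasible combinations rejected
  (D cannot exceed min(p_A q_B, q_A p_B)).
* **GDM outcome**: P(case) = logit⁻¹(baseline + Σ per-allele effects +
  Σ interaction terms + Σ covariate effects). Interaction terms act on
  *mean-centered* dosages (g − 2·MAF): a pure interaction then leaves each
  SNP's marginal odds ratio at ~1 while the joint two-locus penetrance
  differs across cells — the configuration that separates interaction
  detection from marginal association. Covariate effects are applied to
  centered covariates so the baseline logit pins the prevalence; the
  default baseline is 3% GDM (planted genetic/covariate effects raise the
  realized prevalence somewhat above baseline).
* **T2DM outcome**: logit⁻¹(baseline + PRS + diet + PRS×diet +
  breastfeeding terms) with the PRS centered at its cohort mean; default
  baseline 7.6%, the T2DM rate such a control group exhibits.
* **Covariates and lifestyle**: simple parametric families for a
  women-only middle-aged cohort (normal age/BMI, categorical education
  20/23/57%, income 11/44/45%, ~52% regular exercise, right-skewed
  breastfeeding duration).
* **Food frequencies**: intake = loadings · standard-normal latent
  factors + Gaussian noise, shifted non-negative.

All generators are pure functions of (inputs, seed).

What the simulator does **not** emulate: real chip LD structure and
allele-frequency spectra, population stratification, genotyping batch
effects, case ascertainment, or realistic food-intake marginals. Passing
recovery tests therefore demonstrate correctness of the machinery under
the assumed model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS tolerance 1e-8, max 100 iterations; separation
  flagged, not fatal; aliased covariate columns dropped by the fitter,
  but an aliased *interaction* column is an error naming the collinearity.
* EM for haplotype frequencies: tolerance 1e-12 on frequencies, max 1000
  iterations; monomorphic input is an error (r² undefined).
* Monomorphic HWE input returns p = 1 with a flag rather than a test.
* GMDR cells with score sum exactly 0 are low-risk; folds whose test set
  has one outcome class are excluded from fold means with a warning.
* Constant diet scores dichotomize to all-low with a warning; zero-
  variance food groups are dropped before PCA with a warning.
* An analysis stage that empties the candidate set raises an explicit
  "no candidates" error rather than continuing silently.

## Problem sizes used by the test suite

The packaged tests run the recovery experiments at sizes chosen to make
the planted signals unambiguous while keeping the suite quick on a single
core: 10,000 subjects for the epistasis-recovery and null-calibration
experiments (10 and 20 seeded replicates), 20,000 for odds-ratio CI
coverage (100 replicates), 1,000 per replicate across 1,000 replicates
for interaction type-I error and 100,000 for its power check, and
3,000-10,000 for the dietary-pattern experiments. The same quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The exhaustive GMDR search is designed for candidate sets of ~10-20
  SNPs (as produced by the selection funnel); it is not a genome-wide
  epistasis scanner.
* No population-structure correction or mixed models are provided.
* The PRS is unweighted by design; effect-size-weighted scores are out of
  scope.
* Best-model TEBA carries the selection optimism discussed above.
* The per-variant heterozygosity filter excludes common variants at its
  default threshold; see the QC section.
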