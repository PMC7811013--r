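---
title: "Models and methods in mtrpheno"
author: "mtrpheno maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mtrpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrpheno)
```

## The scientific problem

Magnetization transfer imaging probes the macromolecular (largely myelin)
content of brain tissue: the MTR at a voxel, `100 * (M0 - Ms) / M0`,
drops when saturation transfer from bound protons is reduced. In multiple
sclerosis, MTR in lesions and in normal-appearing white and grey matter
(NAWM, NAGM), together with volumetric measures, are (semi-)quantitative
markers of demyelination and neurodegeneration. Two cohort questions
organise the package: longitudinally, how much trait variation is
*inter*-patient versus *intra*-patient over follow-up; cross-sectionally,
how much is attributable to demographics, clinical covariates, or the
genetic susceptibility burden summarized in a polygenic risk score.

## Per-scan trait extraction

`compute_mtr_map()` applies the ratio formula voxel-wise and maps
`M0 <= 0` to missing rather than erroring, since signal-free voxels are
expected outside the head. `derive_normal_appearing_masks()` defines NAGM
and NAWM as GM/WM voxels outside the *sensitive* lesion mask (the mask a
lesion-growing segmentation produces at its most inclusive setting), while
the analysed lesion class is the *specific* mask. When only one lesion
mask is available it is used in both roles; the two-mask distinction
matters only near lesion boundaries.

`summarize_mtr_histogram()` computes four histogram parameters. Numerical
choices, each of which the histogram literature leaves open:

* **Bin width** defaults to 1 MTR unit over [0, 100] and is configurable.
  Peak height and peak location depend on it (roughly proportionally for
  peak height near a smooth mode); median and mean90 do not.
* **Validity range.** Noise can push recomputed MTR below 0 or above 100;
  such voxels are excluded before any statistic, and the peak-height
  denominator is the *included* voxel count, so peak height is a percent
  of the plotted histogram.
* **Percentiles** use the linear-interpolation convention; mean90 averages
  the values lying in the closed interval [P5, P95], i.e. boundary values
  are included.
* **Ties** for the modal bin go to the lowest bin, for determinism.
* An empty tissue class yields a flagged missing trait, not an error,
  because lesion-free scans are legitimate.

Median and mean90 are near-duplicates by construction (both location
measures of the same distribution), and peak location tracks the median at
fixed bin width; `histogram_intercorrelation()` reports this redundancy as
a diagnostic rather than enforcing a trait subset, and the downstream
analyses use median and peak height only.

`compute_volumetrics()` sums soft-segmentation probabilities times voxel
volume (reported in ml); total brain volume is GM + WM + CSF and the WM/GM
percentages are relative to it, so `gm_pct + wm_pct + csf_pct = 100` to
float precision. No resampling is performed anywhere: all volumes of a
scan are assumed voxel-aligned, and co-registration is explicitly out of
scope.

## Longitudinal variance decomposition

All models are ordinary least squares (Gaussian identity link): adjusted
r-squared and overall F-tests, the quantities reported, are OLS
constructs. The generic model is

```
trait ~ patient_id + days_since_first_scan
```

with the patient identifier as a fixed-effect factor (one intercept per
patient) — deliberately not a mixed model, so that "percent of variance
explained" is a plain adjusted r². The contribution of a term is obtained
*by deletion*: adjusted r² of the full model minus adjusted r² of the
model without the term. Relative shares normalize the two raw
contributions to 100%; negative raw contributions (possible, since
adjusted r² penalizes predictors) are floored at zero for the shares while
the raw values stay reported.

Two caveats worth stating. First, deletion with *adjusted* r² inflates the
apparent contribution of a term whose reduced model has many residual
degrees of freedom fewer than the full model (the patient factor costs 32
degrees of freedom at the 33-patient design); when the time share is small
— as under the default generator and in the motivating use case — deletion
shares agree with the realized generative variance split to within ~2
percentage points, which the test suite checks on noise-free data. Second,
the between-patient component of a time trend (patients differ in mean
follow-up time) is attributed to the patient term by deletion; "time"
measures within-patient change.

Time is coded in days since each patient's first scan, never calendar
date. Patients with a single scan are retained (they inform intercepts);
a design in which *every* patient has one scan leaves the time term
undefined and is rejected. The family-wise threshold for this analysis is
0.05/20 = 0.0025 (10 traits, generic + clinical model).

The model p-value reported is the overall F-test; term-wise t-tests are
emitted as supplementary columns since conventions differ between
toolchains.

## Cross-sectional statistics

Scanner protocol always enters as a categorical covariate. Explained
variance by age and gender is the adjusted-r² increment of
`trait ~ age + gender + protocol` over `trait ~ protocol`, with a partial
F-test for the joint block; with a single protocol level the baseline
degrades to intercept-only (logged, not an error). The six cross-tissue
tests are median and peak-height MTR for the pairs lesion–NAWM,
lesion–NAGM and NAWM–NAGM. The association scan performs one
covariate-adjusted test per (trait, predictor) pair and corrects over
`performed tests + 6` so the cross-tissue family shares the budget; at the
full design (10 traits × 10 predictors) this gives 0.05/106 ≈ 0.00047.
Encodings where the source conventions were open: treatment status is a
binary on/off-therapy predictor (the per-drug breakdown is descriptive
only), oligoclonal-band status is binary with unknown as missing, and the
MS severity score enters as a continuous covariate.

## Genetics

Variant QC applies the three standard filters — minor allele frequency
< 1%, call rate < 98%, Hardy–Weinberg exact-test p < 1e-6 — with HWE
computed on hard calls only (fractional dosages are excluded from the HWE
computation, and a variant with no hard calls simply isn't HWE-filtered).
The HWE test is the exact conditional test given allele counts: the
p-value sums the probabilities of all heterozygote counts no more probable
than the observed one, with probabilities computed by the standard
two-term ratio recurrence outward from an interior mode (numerically
stable for large counts). The test suite verifies it against a
log-factorial full enumeration for every genotype table up to 200
chromosomes.

Allele alignment makes every stored weight a non-negative log odds ratio
for the risk-increasing allele: odds ratios below 1 are inverted with the
allele pair swapped, and dosages are reflected (`2 - d`) when the effect
allele is the genotype's other allele. Allele-set mismatches drop the
variant with a logged reason — strand resolution (A/T, C/G flips) is
upstream curation, not attempted here. The PRS is an *unstandardized* sum
of weighted dosages (association inference is scale-invariant either way);
missing dosages are skipped, i.e. each patient's score runs over their
observed variants — mean imputation was considered and rejected as it
changes the score's variance structure silently. Per-variant association
tests are OLS Wald tests on the additively-coded dosage with age, gender
and protocol as covariates; monomorphic variants are skipped and excluded
from the nominal-fraction denominators. Relatedness exclusion is honored
as a boolean flag column in the patient table (identity-by-descent is not
computed), and imputation-quality filtering is an optional metadata column
since imputation itself is out of scope.

## The synthetic cohort generator

The generator's role is to emulate the *statistical structure* the
analyses assume, so that every stage is testable without patient data. The
latent trait model for patient *i*, scan *j*, trait *t* is

```
y_ijt = mu_t + s_t * (b_it + beta_age * z_age_i + beta_gender * f_i
                      + beta_prot * (k_i - 1) + gamma * d_ij + e_ijt)
```

with `b ~ N(0, sigma_between^2)` and `e ~ N(0, sigma_within^2)` on a
common standardized scale, scaled by a per-trait SD and shifted by a
per-trait mean. This additive-Gaussian random-intercept-plus-linear-time
form is the minimal generative model under which the fixed-effect
estimators the package fits are consistent.

Default conditions (chosen once, as the study conditions the generator
emulates):

* **Design**: 33 patients with scans-per-patient distribution
  {2: 29, 3: 3, 5: 1} (72 scans), one scanner protocol, first scan at day
  0, inter-scan intervals Normal(13.2, 7.9) months truncated at 1 month.
  The cross-sectional preset is 213 patients on 6 protocols, one scan
  each, with 3 relatedness exclusions and 1 patient without genetic data
  (209 eligible).
* **Variance structure**: `sigma_between = 1`,
  `sigma_within = sqrt(1/0.95 - 1)` (intraclass correlation 0.95) and a
  small negative drift `gamma = -2.5e-4` per day, so inter-patient
  differences dominate and the time contribution is at the percent level.
* **Covariates**: female probability 0.71, age ~ Normal(40, 12) truncated
  to [19, 71] years, disease duration Gamma-distributed with median ≈ 8
  years, covariate effect sizes default to zero (null covariates).
* **Tissue MTR centers**: lesions 30 < NAGM 32 < NAWM 38 (percent units),
  mimicking the known tissue contrast ordering. No per-tissue means/SDs
  are anchored to published cohort values — none are available for this
  design — so these defaults, like the per-trait means and SDs (e.g.
  total brain 1400 ± 90 ml, WM% 36 ± 2.5), are documented as plausible
  but arbitrary configuration values, not claims.
* **Genetics**: 155 variants (22 flagged HLA), allele frequencies uniform
  on [0.05, 0.5], genotypes Binomial(2, p) per variant — Hardy–Weinberg by
  construction — odds ratios log-normal around 1 with *no* true trait
  effect: the genetic architecture is null by design, matching the
  chance-level benchmark the association scan is tested against.

The voxel-level generator inverts the MTR definition: a target MTR per
voxel around the tissue's latent median, `M0` a positive constant (noise
on `M0` cancels in the ratio), `Ms = M0 * (1 - MTR/100)`. The phantom is a
concentric-sphere brain (WM core ≈ 4000 voxels at the default 32³ grid,
1 mm³ voxels, GM shell, CSF rim) with spherical lesion blobs confined to
WM, and the soft segmentation is the one-hot encoding of the hard labels.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: scanner artifacts, bias fields, motion and
co-registration error; realistic lesion morphology or growth; partial
volume (the soft segmentation is degenerate one-hot); non-Gaussian trait
distributions or floor effects (lesion volume can in principle go
slightly negative under the additive model at its default SD); and any
true genetic effect on traits. Results on real cohorts depend on exactly
these omitted features, so the synthetic results validate the *machinery*
(estimators, accounting identities, error control), not biological
effect sizes.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → traits → longitudinal →
cross-sectional → genetics against an output directory. The `traits` stage
regenerates voxel images for a configurable number of scans (default 3)
and re-extracts traits as a forward/inverse consistency report; the
statistical stages consume the latent trait tables, since the phantom
geometry is fixed across scans and would otherwise collapse volumetric
variance. A single global seed fans out to per-stage child seeds by fixed
offsets, so reruns of stage subsets reproduce byte-identical TSVs; the
JSON manifest records config, seed, input/output MD5 hashes and
timestamps, and a completed stage with unchanged inputs is a no-op.

Problem sizes used throughout the tests and the acceptance script are the
package's own choices: the 33/72 longitudinal design, 213 (209 genetic)
cross-sectional patients, 155 variants, 32³ voxel grids, 200 replicates
for the decomposition calibration check, and full HWE enumeration to 200
chromosomes.

## Known limitations

* Fixed-effect patient intercepts, not mixed models: with two scans per
  patient the adjusted r² of the generic model is an optimistic estimate
  of reproducibility, and deletion shares inherit the adjusted-r²
  small-sample behaviour discussed above.
* The HWE exact test returns 1 for monomorphic variants; such variants are
  excluded by the frequency filter anyway.
* VCF support covers bi-allelic records with GT and/or DS fields only.
* The CLI (`inst/cli/mtrpheno.R`) is a thin wrapper over `run_pipeline()`
  and `render_report()`; the R functions are the primary interface.
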