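# mtrpheno

Quantitative MRI phenotyping for multiple sclerosis (MS) cohorts:
magnetization transfer ratio (MTR) histogram traits and brain volumetrics,
longitudinal inter- vs intra-patient variance decomposition, covariate-adjusted
cross-sectional association scans, and polygenic risk score (PRS) analysis —
plus a synthetic cohort generator so the whole pipeline is testable without
patient data.

## Who this is for

Neuroimaging and imaging-genetics researchers who extract per-scan MTR and
volumetric traits from co-registered MT image pairs and tissue segmentations,
and then ask the standard cohort questions: how much trait variance is
inter-patient vs intra-patient over follow-up, which demographic/clinical
covariates shape the traits cross-sectionally, and whether genetic
susceptibility burden is associated with them.

## What it computes

**Per-scan traits.** From an MT-off/MT-on image pair the MTR map is

    MTR = 100 * (M0 - Ms) / M0

per voxel (voxels with `M0 <= 0` become missing). Within each tissue class —
lesions, normal-appearing white matter (NAWM = WM minus the sensitive lesion
mask), normal-appearing grey matter (NAGM) — the MTR histogram is summarized
by its median, peak height (modal-bin count as percent of included voxels),
peak location and mean90 (mean of values between the 5th and 95th
percentiles). Volumes are soft-segmentation probability sums times voxel
volume; total brain volume is GM + WM + CSF, with WM and GM also expressed as
percent of total. The 10 analysed traits are median and peak-height MTR in
the three tissue classes plus total brain volume, WM%, GM% and lesion volume.

**Longitudinal variance decomposition.** Per trait, the generic OLS model
`trait ~ patient_id + days_since_first_scan` is fitted; the contribution of a
term is adjusted-r² of the full model minus adjusted-r² of the model without
that term, and relative shares normalize the two contributions to 100%. A
clinical model `trait ~ age + gender + disease_duration + time` is reported
side by side.

**Cross-sectional statistics.** Explained variance by age and gender is the
adjusted-r² increment of `trait ~ age + gender + protocol` over
`trait ~ protocol`; cross-tissue MTR relations are covariate-adjusted
regressions between tissue classes; a (trait x predictor) association scan is
Bonferroni-corrected (`alpha / n_tests`).

**Genetics.** Variant QC (minor allele frequency >= 1%, call rate >= 98%,
Hardy–Weinberg exact-test p >= 1e-6), allele alignment so every dosage counts
the risk-increasing allele, PRS as the sum of dosages weighted by log odds
ratios (total, HLA, non-HLA), PRS-trait associations and per-variant
association scans with age, gender and protocol as covariates.

## Worked example

```r
library(mtrpheno)

cfg <- cohort_config(seed = 1)      # 33 patients, 72 scans, one protocol
co  <- simulate_cohort(cfg)
tab <- longitudinal_table(co)
res <- longitudinal_analysis(tab)
res[1:3, c("trait", "generic_adj_r2", "patient_share", "time_share",
           "clinical_adj_r2")]
#>               trait generic_adj_r2 patient_share time_share clinical_adj_r2
#> 1 mtr_median_lesion      0.9577640      98.38127   1.618733      0.04066634
#> 2   mtr_median_nawm      0.9050790      98.73256   1.267438      0.08356267
#> 3   mtr_median_nagm      0.9415567      98.71369   1.286307      0.12016677
```

The generic model explains > 90% of variance in each trait and attributes
~99% of that to inter-patient differences; the clinical covariates alone
explain < 14%. An image round trip:

```r
img <- simulate_scan_images(c(lesion = 30, nawm = 38, nagm = 32), cfg,
                            noise_sd = 1)
tr <- extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                          img$lesion_mask)
tr$mtr_median_nawm
#> [1] 37.97952
```

The recomputed NAWM median recovers the latent value 38 to within the
sampling error of ~4000 voxels. A full run (simulate, trait recovery,
longitudinal, cross-sectional, genetics, with a JSON manifest and Markdown
report):

```r
run_pipeline("out/", pipeline_config(seed = 1))
render_report("out/")
```

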