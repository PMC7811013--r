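Package: mtrpheno
Title: Quantitative MRI Phenotyping for Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative magnetization-transfer-ratio (MTR) and
    volumetric phenotyping of multiple sclerosis cohorts. Computes MTR maps
    from MT-on/MT-off image pairs, tissue-wise MTR histogram summaries
    (median, peak height, peak location, mean90) and brain volumetrics from
    soft segmentations; decomposes longitudinal trait variance into inter-
    and intra-patient contributions with nested linear models; runs
    covariate-adjusted cross-sectional association scans with Bonferroni
    correction; and performs variant quality control (minor allele
    frequency, call rate, Hardy-Weinberg exact test), allele-aligned
    polygenic risk scoring and single-variant association scans. A synthetic
    cohort generator emulates the statistical structure of a longitudinal /
    cross-sectional MS imaging-genetics study so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    RNifti,
    vcfR,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
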