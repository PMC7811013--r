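# Pipeline orchestration: simulate -> traits -> longitudinal ->
# cross-sectional -> genetics, with a JSON run manifest, stage-level
# resumability and a consolidated report.

PIPELINE_STAGES <- c("simulate", "traits", "longitudinal", "cross_sectional",
                     "genetics")

stage_outputs <- function(stage) {
  switch(stage,
    simulate = c("patients_longitudinal.tsv", "scans_longitudinal.tsv",
                 "patients_cross_sectional.tsv", "scans_cross_sectional.tsv",
                 "dosages.tsv", "weights.tsv"),
    traits = "trait_recovery.tsv",
    longitudinal = c("longitudinal_decomposition.tsv",
                     "longitudinal_decomposition.json"),
    cross_sectional = c("age_gender_variance.tsv", "cross_tissue.tsv",
                        "clinical_scan.tsv"),
    genetics = c("variant_qc.tsv", "prs.tsv", "prs_associations.tsv",
                 "variant_scan.tsv", "nominal_fractions.tsv"))
}

stage_inputs <- function(stage) {
  switch(stage,
    simulate = character(),
    traits = "scans_longitudinal.tsv",
    longitudinal = c("patients_longitudinal.tsv", "scans_longitudinal.tsv"),
    cross_sectional = c("patients_cross_sectional.tsv",
                        "scans_cross_sectional.tsv"),
    genetics = c("patients_cross_sectional.tsv", "scans_cross_sectional.tsv",
                 "dosages.tsv", "weights.tsv"))
}

#' Pipeline configuration
#'
#' Bundles the longitudinal and cross-sectional generator configurations
#' and a global seed. The global seed is fanned out to per-stage child
#' seeds by fixed offsets (longitudinal cohort: seed; cross-sectional
#' cohort: seed + 1; images: seed + 2; genotypes: seed + 1001) so that
#' stage subsets rerun reproducibly.
#'
#' @param seed global integer seed.
#' @param longitudinal named list of [cohort_config()] overrides for the
#'   longitudinal cohort.
#' @param cross_sectional named list of [cross_sectional_config()]
#'   overrides.
#' @param n_image_scans number of longitudinal scans for which voxel-level
#'   images are generated and traits re-extracted in the `traits` stage.
#' @param noise_sd voxel MTR noise SD used by the `traits` stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, longitudinal = list(),
                            cross_sectional = list(), n_image_scans = 3,
                            noise_sd = 1) {
  seed <- as.integer(seed)
  cfg_long <- do.call(cohort_config, c(list(seed = seed), longitudinal))
  cfg_cs <- do.call(cross_sectional_config,
                    c(list(seed = seed + 1L), cross_sectional))
  structure(list(seed = seed, longitudinal = cfg_long,
                 cross_sectional = cfg_cs,
                 n_image_scans = n_image_scans, noise_sd = noise_sd),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `seed`, `n_image_scans`, `noise_sd`, and the nested
#' maps `longitudinal` and `cross_sectional`, whose entries address any
#' field of [cohort_config()] (vectors like `scans_per_patient` are YAML
#' maps from scan count to patient count).
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fix_named <- function(lst) {
    for (f in c("scans_per_patient", "trait_means", "trait_sds",
                "tissue_mtr_centers", "interval_months"))
      if (!is.null(lst[[f]])) lst[[f]] <- unlist(lst[[f]])
    lst
  }
  pipeline_config(seed = y$seed %||% 1L,
                  longitudinal = fix_named(y$longitudinal %||% list()),
                  cross_sectional = fix_named(y$cross_sectional %||% list()),
                  n_image_scans = y$n_image_scans %||% 3,
                  noise_sd = y$noise_sd %||% 1)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order against `outdir`:
#' `simulate` (cohorts, latent scan traits, genotypes, weights), `traits`
#' (voxel-level image generation and trait re-extraction for a subset of
#' scans, as a forward/inverse consistency report), `longitudinal`
#' (per-trait variance decomposition and clinical models),
#' `cross_sectional` (age/gender explained variance, cross-tissue MTR
#' tests, clinical association scan) and `genetics` (variant QC, allele
#' alignment, PRS, PRS-trait associations, single-variant scan). A JSON
#' manifest records the configuration, seed, per-stage input/output MD5
#' hashes, package version and timestamps; a completed stage whose inputs
#' are unchanged is skipped unless `force = TRUE`.
#'
#' @param outdir output directory (created if absent).
#' @param config a [pipeline_config()], or a path to its YAML form.
#' @param stages subset of `simulate`, `traits`, `longitudinal`,
#'   `cross_sectional`, `genetics` (always executed in that order).
#' @param force rerun stages even when up to date.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(outdir, config = pipeline_config(),
                         stages = PIPELINE_STAGES, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
    list(stages = list())
  manifest$seed <- config$seed
  manifest$version <- as.character(packageVersion("mtrpheno"))
  manifest$config <- config_snapshot(config)

  for (st in stages) {
    ins <- file.path(outdir, stage_inputs(st))
    if (!all(file.exists(ins)))
      stop(sprintf("dependency error: stage '%s' requires missing input(s) %s%s",
                   st, paste(basename(ins[!file.exists(ins)]), collapse = ", "),
                   " (run the 'simulate' stage first)"))
    in_md5 <- unname(tools::md5sum(ins))
    outs <- file.path(outdir, stage_outputs(st))
    prev <- manifest$stages[[st]]
    if (!force && all(file.exists(outs)) && !is.null(prev) &&
        identical(as.character(unlist(prev$input_md5)), as.character(in_md5))) {
      message("stage '", st, "' up to date, skipped")
      next
    }
    message("running stage '", st, "'")
    switch(st,
      simulate = stage_simulate(outdir, config),
      traits = stage_traits(outdir, config),
      longitudinal = stage_longitudinal(outdir),
      cross_sectional = stage_cross_sectional(outdir),
      genetics = stage_genetics(outdir))
    manifest$stages[[st]] <- list(
      input_md5 = as.list(in_md5),
      output_md5 = as.list(unname(tools::md5sum(outs))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  strip <- function(x) lapply(unclass(x), function(v)
    if (is.factor(v)) as.character(v) else v)
  list(seed = config$seed, n_image_scans = config$n_image_scans,
       noise_sd = config$noise_sd,
       longitudinal = strip(config$longitudinal),
       cross_sectional = strip(config$cross_sectional))
}

stage_simulate <- function(outdir, config) {
  long <- simulate_cohort(config$longitudinal)
  cs <- simulate_cohort(config$cross_sectional)
  write_tsv(long$patients, file.path(outdir, "patients_longitudinal.tsv"))
  write_tsv(long$scans, file.path(outdir, "scans_longitudinal.tsv"))
  write_tsv(cs$patients, file.path(outdir, "patients_cross_sectional.tsv"))
  write_tsv(cs$scans, file.path(outdir, "scans_cross_sectional.tsv"))
  gen_ids <- cs$patients$patient_id[cs$patients$genetic_available]
  gen <- simulate_genotypes(config$cross_sectional, gen_ids,
                            seed = config$seed + 1001L)
  write_dosage_tsv(gen$genotypes, file.path(outdir, "dosages.tsv"))
  write_weights_tsv(gen$weights, file.path(outdir, "weights.tsv"))
  invisible(NULL)
}

stage_traits <- function(outdir, config) {
  scans <- read_tsv(file.path(outdir, "scans_longitudinal.tsv"))
  n <- min(config$n_image_scans, nrow(scans))
  local_seed(config$seed + 2L)
  rows <- lapply(seq_len(n), function(i) {
    lat <- c(lesion = scans$mtr_median_lesion[i],
             nawm = scans$mtr_median_nawm[i],
             nagm = scans$mtr_median_nagm[i])
    img <- simulate_scan_images(lat, config$longitudinal,
                                noise_sd = config$noise_sd)
    tr <- extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                              img$lesion_mask,
                              metadata = list(
                                patient_id = scans$patient_id[i],
                                days_since_first = scans$days_since_first[i],
                                protocol = scans$protocol[i]))
    data.frame(patient_id = scans$patient_id[i],
               scan_index = scans$scan_index[i],
               latent_lesion = lat[["lesion"]], latent_nawm = lat[["nawm"]],
               latent_nagm = lat[["nagm"]],
               recovered_lesion = tr$mtr_median_lesion,
               recovered_nawm = tr$mtr_median_nawm,
               recovered_nagm = tr$mtr_median_nagm,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$abs_error_nawm <- abs(rec$recovered_nawm - rec$latent_nawm)
  write_tsv(rec, file.path(outdir, "trait_recovery.tsv"))
  invisible(NULL)
}

read_cohort_tables <- function(outdir, which = c("longitudinal",
                                                 "cross_sectional")) {
  which <- match.arg(which)
  pt <- read_tsv(file.path(outdir, sprintf("patients_%s.tsv", which)))
  sc <- read_tsv(file.path(outdir, sprintf("scans_%s.tsv", which)))
  pt$gender <- factor(pt$gender, levels = c("female", "male"))
  pt$protocol <- factor(pt$protocol)
  pt$ocb_status <- factor(pt$ocb_status, levels = c("negative", "positive"))
  pt$treatment <- factor(pt$treatment, levels = c("off", "on"))
  sc$protocol <- factor(sc$protocol)
  list(patients = pt, scans = sc)
}

stage_longitudinal <- function(outdir) {
  tabs <- read_cohort_tables(outdir, "longitudinal")
  res <- longitudinal_analysis(longitudinal_table(tabs))
  write_tsv(res, file.path(outdir, "longitudinal_decomposition.tsv"))
  jsonlite::write_json(res, file.path(outdir, "longitudinal_decomposition.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_cross_sectional <- function(outdir) {
  tabs <- read_cohort_tables(outdir, "cross_sectional")
  tab <- cross_sectional_table(tabs)
  ag <- do.call(rbind, lapply(trait_names(), function(tr)
    explained_variance_by_age_gender(tab, tr)))
  ag$delta_pct <- 100 * ag$delta_adj_r2
  write_tsv(ag, file.path(outdir, "age_gender_variance.tsv"))
  write_tsv(cross_tissue_scan(tab), file.path(outdir, "cross_tissue.tsv"))
  cl <- clinical_association_scan(tab)
  write_tsv(cl, file.path(outdir, "clinical_scan.tsv"))
  invisible(NULL)
}

stage_genetics <- function(outdir) {
  tabs <- read_cohort_tables(outdir, "cross_sectional")
  geno <- read_dosage_tsv(file.path(outdir, "dosages.tsv"))
  weights <- read_weights_tsv(file.path(outdir, "weights.tsv"))
  qc <- variant_qc(geno)
  write_tsv(qc, file.path(outdir, "variant_qc.tsv"))
  kept <- qc$variant_id[qc$kept]
  geno_kept <- genotype_matrix(
    geno$dosages[, kept, drop = FALSE],
    geno$variants[geno$variants$variant_id %in% kept, , drop = FALSE])
  aligned <- align_effect_alleles(geno_kept,
                                  weights[weights$variant_id %in% kept, ])
  # relatedness exclusion: flagged patients leave the genetic analysis
  tab <- cross_sectional_table(tabs)
  eligible <- tab$patient_id[!tab$related_excluded &
                               tab$patient_id %in% rownames(aligned$dosages)]
  aligned$dosages <- aligned$dosages[eligible, , drop = FALSE]
  scores <- data.frame(patient_id = eligible,
                       prs_total = compute_prs(aligned, "all"),
                       prs_hla = compute_prs(aligned, "HLA"),
                       prs_nonhla = compute_prs(aligned, "non-HLA"),
                       stringsAsFactors = FALSE)
  write_tsv(scores, file.path(outdir, "prs.tsv"))
  assoc <- prs_trait_association(scores, tab)
  thr <- bonferroni_threshold(0.05, nrow(assoc))
  assoc$threshold <- thr
  assoc$significant <- assoc$p <= thr
  write_tsv(assoc, file.path(outdir, "prs_associations.tsv"))
  scan <- single_variant_scan(aligned, tab[tab$patient_id %in% eligible, ])
  write_tsv(scan$results, file.path(outdir, "variant_scan.tsv"))
  write_tsv(scan$nominal, file.path(outdir, "nominal_fractions.tsv"))
  invisible(NULL)
}

#' Render a consolidated report from pipeline outputs
#'
#' Re-reads the stage TSVs under `outdir` and writes `report.md` and
#' `report.json`: the Bonferroni thresholds used, the per-trait
#' longitudinal decomposition (generic vs clinical model), the age/gender
#' explained-variance and cross-tissue tables, and the genetics
#' nominal-significance fractions. Sections whose stage has not run are
#' marked absent rather than failing.
#'
#' @param outdir pipeline output directory.
#' @return list with the report sections, invisibly.
#' @export
render_report <- function(outdir) {
  if (!length(list.files(outdir)))
    stop("no stage outputs found in ", outdir)
  grab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) read_tsv(p) else NULL
  }
  long <- grab("longitudinal_decomposition.tsv")
  ag <- grab("age_gender_variance.tsv")
  ct <- grab("cross_tissue.tsv")
  cl <- grab("clinical_scan.tsv")
  nom <- grab("nominal_fractions.tsv")
  qc <- grab("variant_qc.tsv")

  md <- c("# Quantitative MRI phenotyping report", "")
  fmt_tab <- function(df, cols, digits = 3) {
    df <- df[, cols, drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste("|", paste(cols, collapse = " | "), "|"),
      paste("|", paste(rep("---", length(cols)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  md <- c(md, "## Multiple-testing thresholds", "",
          sprintf("- Longitudinal family (10 traits x 2 models): P <= %.4g",
                  bonferroni_threshold(0.05, 20)),
          sprintf("- Cross-sectional family (10 x 10 scans + 6 cross-tissue): P <= %.4g",
                  bonferroni_threshold(0.05, 106)), "")
  if (!is.null(long))
    md <- c(md, "## Longitudinal variance decomposition", "",
            fmt_tab(long, c("trait", "generic_adj_r2", "patient_share",
                            "time_share", "clinical_adj_r2")), "")
  else md <- c(md, "## Longitudinal variance decomposition", "", "_absent_", "")
  if (!is.null(ag))
    md <- c(md, "## Variance explained by age and gender", "",
            fmt_tab(ag, c("trait", "delta_pct", "p", "n")), "")
  else md <- c(md, "## Variance explained by age and gender", "", "_absent_", "")
  if (!is.null(ct))
    md <- c(md, "## Cross-tissue MTR correlations", "",
            fmt_tab(ct, c("trait", "predictor", "adj_r2_full",
                          "delta_adj_r2", "p")), "")
  else md <- c(md, "## Cross-tissue MTR correlations", "", "_absent_", "")
  if (!is.null(nom)) {
    md <- c(md, "## Genetics", "",
            if (!is.null(qc)) sprintf("- variants kept after QC: %d of %d",
                                      sum(qc$kept), nrow(qc)),
            fmt_tab(nom, c("category", "n_tests", "n_nominal",
                           "nominal_fraction")), "")
  } else md <- c(md, "## Genetics", "", "_absent_", "")
  writeLines(md, file.path(outdir, "report.md"))
  report <- list(thresholds = list(longitudinal = bonferroni_threshold(0.05, 20),
                                   cross_sectional = bonferroni_threshold(0.05, 106)),
                 longitudinal = long, age_gender = ag, cross_tissue = ct,
                 clinical_scan = cl, nominal_fractions = nom)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
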