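# Synthetic cohort generator.
#
# Emulates the statistical structure of a longitudinal / cross-sectional MS
# imaging-genetics study: per-patient latent MRI traits with dominant
# between-patient variance and small within-patient drift, voxel-level MT
# image pairs consistent with the latent tissue medians, covariates with
# realistic imbalance, and Hardy-Weinberg-consistent genotypes with null
# trait effects.

#' Configuration for the synthetic cohort generator
#'
#' The latent trait model for patient i, scan j and trait t is
#' \deqn{y_{ijt} = \mu_t + s_t (b_{it} + \beta_{age} z_{age,i}
#'   + \beta_{gender} f_i + \beta_{prot} (k_i - 1) + \gamma d_{ij} + e_{ijt})}
#' with random intercept \eqn{b_{it} \sim N(0, \sigma_b^2)}, residual
#' \eqn{e_{ijt} \sim N(0, \sigma_w^2)}, days since first scan \eqn{d_{ij}}
#' (0 at the first scan), standardized age \eqn{z_{age} = (age - 40)/10},
#' female indicator \eqn{f}, protocol index \eqn{k}, per-trait grand mean
#' \eqn{\mu_t} and scale \eqn{s_t}. All structure is therefore on a common
#' standardized scale; defaults give intraclass correlation
#' \eqn{\sigma_b^2/(\sigma_b^2+\sigma_w^2) = 0.95} and null covariate
#' effects.
#'
#' @param n_patients number of patients.
#' @param scans_per_patient named integer vector: names are scans-per-patient
#'   counts, values are how many patients have that many scans; values must
#'   sum to `n_patients`. Default `c("2" = 29, "3" = 3, "5" = 1)` (33
#'   patients, 72 scans).
#' @param n_protocols number of scanner protocols; with 1, every patient is
#'   on the same protocol (longitudinal design), otherwise protocols are
#'   assigned multinomially, one per patient.
#' @param image_shape voxel grid dimensions for simulated images.
#' @param voxel_size mm per axis.
#' @param sigma_between between-patient SD of each latent trait (standardized).
#' @param sigma_within residual within-patient SD (standardized).
#' @param time_slope latent trait change per day (standardized units).
#' @param beta_age,beta_gender,beta_protocol covariate effect sizes
#'   (standardized units per standardized-age unit / female / protocol step).
#' @param trait_means,trait_sds named numeric vectors over [trait_names()]:
#'   grand mean and scale of each trait in its natural units.
#' @param tissue_mtr_centers per-tissue mean MTR in percent units, names
#'   `lesion`, `nawm`, `nagm`; each must lie in (0, 100). Defaults follow
#'   the known tissue contrast ordering lesion < NAGM < NAWM.
#' @param csf_mtr,m0_level CSF MTR (percent) and MT-off signal level used by
#'   the image generator.
#' @param interval_months mean and SD (months) of the between-scan interval,
#'   truncated at 1 month.
#' @param p_female probability a patient is female.
#' @param n_variants,n_hla number of risk variants and how many of them are
#'   flagged as HLA-region variants.
#' @param maf_range interval of minor allele frequencies, subset of (0, 0.5].
#' @param missing_rate per-call genotype missingness rate.
#' @param n_related_excluded patients flagged as excluded from genetic
#'   analysis for cryptic relatedness (a boolean flag; identity-by-descent
#'   itself is not computed).
#' @param n_no_genetic patients without genetic data.
#' @param seed RNG seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 33,
                          scans_per_patient = c("2" = 29, "3" = 3, "5" = 1),
                          n_protocols = 1,
                          image_shape = c(32, 32, 32),
                          voxel_size = c(1, 1, 1),
                          sigma_between = 1,
                          sigma_within = sqrt(1 / 0.95 - 1),
                          time_slope = -0.00025,
                          beta_age = 0, beta_gender = 0, beta_protocol = 0,
                          trait_means = NULL, trait_sds = NULL,
                          tissue_mtr_centers = c(lesion = 30, nawm = 38, nagm = 32),
                          csf_mtr = 5, m0_level = 1000,
                          interval_months = c(mean = 13.2, sd = 7.9),
                          p_female = 0.71,
                          n_variants = 155, n_hla = 22,
                          maf_range = c(0.05, 0.5),
                          missing_rate = 0,
                          n_related_excluded = 0, n_no_genetic = 0,
                          seed = 1L) {
  default_means <- c(mtr_median_lesion = 30, mtr_median_nawm = 38,
                     mtr_median_nagm = 32, mtr_peakh_lesion = 5,
                     mtr_peakh_nawm = 11, mtr_peakh_nagm = 8,
                     total_brain_volume = 1400, wm_pct = 36, gm_pct = 44,
                     lesion_volume = 12)
  default_sds <- c(mtr_median_lesion = 1.2, mtr_median_nawm = 0.8,
                   mtr_median_nagm = 0.8, mtr_peakh_lesion = 1.0,
                   mtr_peakh_nawm = 1.5, mtr_peakh_nagm = 1.2,
                   total_brain_volume = 90, wm_pct = 2.5, gm_pct = 2.5,
                   lesion_volume = 5)
  trait_means <- modify_named(default_means, trait_means)
  trait_sds <- modify_named(default_sds, trait_sds)
  # per-tissue centers drive both the latent medians and the image generator
  trait_means[c("mtr_median_lesion", "mtr_median_nawm", "mtr_median_nagm")] <-
    tissue_mtr_centers[c("lesion", "nawm", "nagm")]

  scans_per_patient <- scans_per_patient[order(as.integer(names(scans_per_patient)))]
  cfg <- list(n_patients = as.integer(n_patients),
              scans_per_patient = scans_per_patient,
              n_protocols = as.integer(n_protocols),
              image_shape = as.integer(image_shape), voxel_size = voxel_size,
              sigma_between = sigma_between, sigma_within = sigma_within,
              time_slope = time_slope, beta_age = beta_age,
              beta_gender = beta_gender, beta_protocol = beta_protocol,
              trait_means = trait_means, trait_sds = trait_sds,
              tissue_mtr_centers = tissue_mtr_centers,
              csf_mtr = csf_mtr, m0_level = m0_level,
              interval_months = interval_months, p_female = p_female,
              n_variants = as.integer(n_variants), n_hla = as.integer(n_hla),
              maf_range = maf_range, missing_rate = missing_rate,
              n_related_excluded = as.integer(n_related_excluded),
              n_no_genetic = as.integer(n_no_genetic),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Configuration preset for a cross-sectional cohort
#'
#' One scan per patient, several scanner protocols assigned multinomially.
#' Defaults to 213 patients on 6 protocols, with 3 patients flagged for
#' relatedness exclusion and 1 without genetic data (209 eligible for
#' genetic analysis).
#'
#' @param n_patients number of patients.
#' @param n_protocols number of protocols.
#' @param n_related_excluded,n_no_genetic genetics exclusions, see
#'   [cohort_config()].
#' @param ... further arguments to [cohort_config()].
#' @return a `cohort_config`.
#' @export
cross_sectional_config <- function(n_patients = 213, n_protocols = 6,
                                   n_related_excluded = 3, n_no_genetic = 1,
                                   ...) {
  cohort_config(n_patients = n_patients,
                scans_per_patient = setNames(n_patients, "1"),
                n_protocols = n_protocols,
                n_related_excluded = n_related_excluded,
                n_no_genetic = n_no_genetic, ...)
}

modify_named <- function(base, new) {
  if (is.null(new)) return(base)
  bad <- setdiff(names(new), names(base))
  if (length(bad)) stop("unknown trait names: ", paste(bad, collapse = ", "))
  base[names(new)] <- as.numeric(new)
  base
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1) stop("configuration error: n_patients must be >= 1")
    if (sum(scans_per_patient) != n_patients)
      stop(sprintf(paste0("configuration error: scans_per_patient counts sum ",
                          "to %d, not n_patients = %d"),
                   sum(scans_per_patient), n_patients))
    if (any(is.na(as.integer(names(scans_per_patient)))) ||
        any(as.integer(names(scans_per_patient)) < 1))
      stop("configuration error: scans_per_patient names must be positive counts")
    if (sigma_between < 0 || sigma_within < 0)
      stop("configuration error: SDs must be >= 0")
    if (any(image_shape < 8))
      stop("configuration error: image_shape must be >= 8 voxels per axis")
    if (!all(c("lesion", "nawm", "nagm") %in% names(tissue_mtr_centers)) ||
        any(tissue_mtr_centers <= 0) || any(tissue_mtr_centers >= 100))
      stop("configuration error: tissue MTR centers must lie in (0, 100)")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("configuration error: maf_range must be within (0, 0.5]")
    if (n_hla < 0 || n_hla > n_variants)
      stop("configuration error: n_hla must be in [0, n_variants]")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("configuration error: missing_rate must be in [0, 1)")
  })
  invisible(cfg)
}

DAYS_PER_MONTH <- 30.4375

#' Simulate a cohort of patients and latent scan traits
#'
#' Draws patient covariates (age, gender, disease duration, protocol,
#' clinical variables) and the latent 10-trait vector for every scan under
#' the additive random-intercept model documented in [cohort_config()].
#' The first scan of each patient is at day 0; subsequent intervals are
#' Normal(`interval_months`) truncated at one month.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `patients` (one
#'   row per patient: demographics, clinical covariates, genetics exclusion
#'   flags) and `scans` (one row per scan: `patient_id`, `scan_index`,
#'   `days_since_first`, `protocol` and the 10 trait columns of
#'   [trait_names()]). The realized latent components (random intercepts
#'   `b`, residuals `eps`) are attached as `attr(scans, "latent")` for
#'   ground-truth checks. Reproducible: identical config (incl. seed) gives
#'   identical tables.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  local_seed(config$seed)
  n <- config$n_patients
  traits <- trait_names()

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_at_first_scan = pmin(pmax(rnorm(n, 40, 12), 19), 71),
    gender = factor(ifelse(runif(n) < config$p_female, "female", "male"),
                    levels = c("female", "male")),
    disease_duration = pmin(rgamma(n, shape = 1.6, scale = 6.5), 43),
    protocol = factor(sprintf("prot%d", sample.int(config$n_protocols, n,
                                                   replace = TRUE)),
                      levels = sprintf("prot%d", seq_len(config$n_protocols))),
    ocb_status = factor(sample(c("positive", "negative", NA), n, replace = TRUE,
                               prob = c(175, 18, 20) / 213),
                        levels = c("negative", "positive")),
    igg_index = rlnorm(n, log(0.9), 0.35),
    msss = pmin(pmax(rlnorm(n, log(1.6), 0.9), 0.11), 9.45),
    treatment = factor(ifelse(runif(n) < 0.625, "on", "off"),
                       levels = c("off", "on")),
    related_excluded = FALSE,
    genetic_available = TRUE,
    stringsAsFactors = FALSE
  )
  # genetics exclusions: cryptic relatedness (IBD flag, not computed here)
  # and absent genetic data
  n_excl <- config$n_related_excluded + config$n_no_genetic
  if (n_excl > 0) {
    who <- sample.int(n, n_excl)
    patients$related_excluded[who[seq_len(config$n_related_excluded)]] <- TRUE
    if (config$n_no_genetic > 0)
      patients$genetic_available[
        who[config$n_related_excluded + seq_len(config$n_no_genetic)]] <- FALSE
  }

  # expand scans-per-patient distribution in patient order
  n_scans_each <- rep(as.integer(names(config$scans_per_patient)),
                      times = config$scans_per_patient)
  total_scans <- sum(n_scans_each)

  b <- matrix(rnorm(n * length(traits), 0, config$sigma_between), nrow = n,
              dimnames = list(patients$patient_id, traits))
  eps <- matrix(rnorm(total_scans * length(traits), 0, config$sigma_within),
                nrow = total_scans, dimnames = list(NULL, traits))

  rows <- vector("list", n)
  scan_row <- 0L
  for (i in seq_len(n)) {
    k <- n_scans_each[i]
    intervals <- if (k > 1)
      pmax(rnorm(k - 1, config$interval_months["mean"],
                 config$interval_months["sd"]), 1) * DAYS_PER_MONTH
      else numeric(0)
    days <- c(0, cumsum(intervals))
    z_age <- (patients$age_at_first_scan[i] - 40) / 10
    fixed <- config$beta_age * z_age +
      config$beta_gender * (patients$gender[i] == "female") +
      config$beta_protocol * (as.integer(patients$protocol[i]) - 1)
    lin <- outer(rep(1, k), b[i, ] + fixed) +
      outer(days * config$time_slope, rep(1, length(traits))) +
      eps[scan_row + seq_len(k), , drop = FALSE]
    vals <- sweep(sweep(lin, 2, config$trait_sds[traits], `*`),
                  2, config$trait_means[traits], `+`)
    colnames(vals) <- traits
    rows[[i]] <- data.frame(
      patient_id = patients$patient_id[i], scan_index = seq_len(k),
      days_since_first = days, protocol = patients$protocol[i],
      vals, stringsAsFactors = FALSE, row.names = NULL)
    scan_row <- scan_row + k
  }
  scans <- do.call(rbind, rows)
  attr(scans, "latent") <- list(b = b, eps = eps)
  structure(list(patients = patients, scans = scans, config = config),
            class = "synthetic_cohort")
}

#' Descriptive summary of a patient table
#'
#' Demographics-table arithmetic: gender split (percent female to one
#' decimal), medians and ranges of age, disease duration and MSSS, and the
#' treatment / OCB breakdown.
#'
#' @param patients patient table (`patients` element of a cohort, or a
#'   compatible data.frame with at least `gender`).
#' @return named list of descriptive statistics.
#' @export
cohort_summary <- function(patients) {
  n <- nrow(patients)
  n_female <- sum(patients$gender == "female", na.rm = TRUE)
  med_range <- function(x) if (is.null(x)) NULL else
    c(median = median(x, na.rm = TRUE), min = min(x, na.rm = TRUE),
      max = max(x, na.rm = TRUE))
  list(
    n_patients = n,
    n_female = n_female, n_male = n - n_female,
    pct_female = round(100 * n_female / n, 1),
    age = med_range(patients$age_at_first_scan),
    disease_duration = med_range(patients$disease_duration),
    msss = med_range(patients$msss),
    pct_on_treatment = if (!is.null(patients$treatment))
      round(100 * mean(patients$treatment == "on", na.rm = TRUE), 1) else NULL,
    pct_ocb_positive = if (!is.null(patients$ocb_status))
      round(100 * mean(patients$ocb_status == "positive", na.rm = TRUE), 1)
      else NULL
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d scans, %d protocol(s)\n",
              nrow(x$patients), nrow(x$scans), nlevels(x$patients$protocol)))
  invisible(x)
}

# concentric-sphere brain geometry: WM core, GM shell, CSF rim
brain_geometry <- function(shape) {
  half <- min(shape) / 2
  ctr <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  hard <- integer(length(r))
  hard[r <= 0.92 * half] <- SEG_LABELS[["csf"]]
  hard[r <= 0.80 * half] <- SEG_LABELS[["gm"]]
  hard[r <= 0.62 * half] <- SEG_LABELS[["wm"]]
  list(hard = array(hard, shape), coords = g, r = r)
}

#' Simulate the MT image pair and segmentations for one scan
#'
#' Inverse model of the MTR definition: each voxel receives a target MTR
#' drawn around its tissue's latent median (`Normal(center, noise_sd)`),
#' the MT-off image `M0` is set to a positive constant (plus optional
#' signal noise, which cancels in the ratio) and `Ms = M0 (1 - MTR/100)`,
#' so that recomputing `100 (M0 - Ms)/M0` recovers the per-voxel target
#' exactly. The phantom is a concentric-sphere brain (WM core, GM shell,
#' CSF rim) with spherical lesion blobs placed inside WM; outside the brain
#' `M0 = 0`, which maps to missing MTR. The soft segmentation is the
#' one-hot encoding of the hard labels and hence sums to 1 at every brain
#' voxel.
#'
#' @param latent_medians named numeric: per-tissue median MTR in percent,
#'   names `lesion`, `nawm`, `nagm`; all must lie in (0, 100).
#' @param config a [cohort_config()] supplying grid shape, voxel size, CSF
#'   MTR and M0 level.
#' @param noise_sd SD of the per-voxel MTR draw (0 gives the exact
#'   noise-free phantom).
#' @param n_lesions number of spherical lesion blobs.
#' @param m0_noise_sd SD of multiplicative-free additive noise on M0.
#' @return list of class `scan_images`: `m0`, `ms` (`volume_image`),
#'   `hard_seg` label array, `soft_seg` (list `gm`, `wm`, `csf`),
#'   `lesion_mask` (logical; used as both the sensitive and specific mask),
#'   `voxel_size`.
#' @export
simulate_scan_images <- function(latent_medians, config = cohort_config(),
                                 noise_sd = 1, n_lesions = 3,
                                 m0_noise_sd = 0) {
  req <- c("lesion", "nawm", "nagm")
  if (!all(req %in% names(latent_medians)))
    stop("latent_medians must be named lesion, nawm, nagm")
  if (any(latent_medians[req] <= 0) || any(latent_medians[req] >= 100))
    stop("domain error: latent medians must lie in (0, 100)")
  shape <- config$image_shape
  geo <- brain_geometry(shape)
  hard <- geo$hard

  lesion <- array(FALSE, shape)
  wm_idx <- which(hard == SEG_LABELS[["wm"]])
  if (n_lesions > 0 && length(wm_idx)) {
    centers <- sample(wm_idx, n_lesions, replace = length(wm_idx) < n_lesions)
    for (cidx in centers) {
      cc <- arrayInd(cidx, shape)
      rad <- runif(1, 1.5, 3)
      d2 <- (geo$coords$x - cc[1])^2 + (geo$coords$y - cc[2])^2 +
        (geo$coords$z - cc[3])^2
      lesion <- lesion | array(d2 <= rad^2, shape)
    }
    lesion <- lesion & (hard == SEG_LABELS[["wm"]])  # blobs confined to WM
  }

  target <- array(NA_real_, shape)
  target[hard == SEG_LABELS[["csf"]]] <- config$csf_mtr
  target[hard == SEG_LABELS[["gm"]]] <- latent_medians[["nagm"]]
  target[hard == SEG_LABELS[["wm"]]] <- latent_medians[["nawm"]]
  target[lesion] <- latent_medians[["lesion"]]
  brain <- hard != SEG_LABELS[["background"]]
  if (noise_sd > 0)
    target[brain] <- target[brain] + rnorm(sum(brain), 0, noise_sd)

  m0 <- array(0, shape)
  m0[brain] <- config$m0_level
  if (m0_noise_sd > 0)
    m0[brain] <- pmax(m0[brain] + rnorm(sum(brain), 0, m0_noise_sd),
                      config$m0_level / 100)
  ms <- array(0, shape)
  ms[brain] <- m0[brain] * (1 - target[brain] / 100)

  soft <- lapply(c(gm = "gm", wm = "wm", csf = "csf"), function(cl)
    array(as.numeric(hard == SEG_LABELS[[cl]]), shape))
  structure(list(
    m0 = volume_image(m0, config$voxel_size),
    ms = volume_image(ms, config$voxel_size),
    hard_seg = hard, soft_seg = soft, lesion_mask = lesion,
    voxel_size = config$voxel_size
  ), class = "scan_images")
}

#' Write one scan's simulated volumes as NIfTI files
#'
#' Emits `<prefix>_m0.nii.gz`, `<prefix>_ms.nii.gz`,
#' `<prefix>_hardseg.nii.gz`, `<prefix>_soft_{gm,wm,csf}.nii.gz` and
#' `<prefix>_lesion.nii.gz` under `dir`.
#'
#' @param images a [simulate_scan_images()] result.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scan_images <- function(images, dir, prefix = "scan") {
  stopifnot(inherits(images, "scan_images"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- images$voxel_size
  vols <- c(list(m0 = images$m0, ms = images$ms,
                 hardseg = volume_image(images$hard_seg + 0, vox),
                 lesion = volume_image(images$lesion_mask + 0, vox)),
            setNames(lapply(images$soft_seg, volume_image, voxel_size = vox),
                     paste0("soft_", names(images$soft_seg))))
  paths <- vapply(names(vols), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    write_volume(vols[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Simulate genotype dosages and a risk-variant weight table
#'
#' Each variant's allele frequency is drawn uniformly from `maf_range` and
#' genotypes are Binomial(2, p) per patient, so Hardy-Weinberg equilibrium
#' holds by construction. Odds ratios are drawn log-normally around 1 and
#' carry no true trait effect (a null genetic architecture). The first
#' `n_hla` variants are flagged as HLA-region variants.
#'
#' @param config a [cohort_config()] (uses `n_variants`, `n_hla`,
#'   `maf_range`, `missing_rate`).
#' @param patient_ids character vector of patient identifiers.
#' @param seed optional seed; defaults to `config$seed + 1000` so genotype
#'   draws are decoupled from the trait draws.
#' @return list with `genotypes` (a `genotype_matrix`: patients x variants
#'   dosage matrix with per-variant metadata) and `weights` (data.frame
#'   `variant_id`, `effect_allele`, `other_allele`, `odds_ratio`,
#'   `category`).
#' @export
simulate_genotypes <- function(config, patient_ids, seed = NULL) {
  stopifnot(config$n_variants >= 1)
  local_seed(seed %||% (config$seed + 1000))
  n <- length(patient_ids)
  m <- config$n_variants
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  # unambiguous allele pairs only (strand resolution is out of scope)
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  al <- do.call(rbind, pairs[sample.int(4, m, replace = TRUE)])
  hla <- seq_len(m) <= config$n_hla
  ids <- ifelse(hla, sprintf("hla_%03d", seq_len(m)),
                sprintf("snp_%03d", seq_len(m)))
  dos <- vapply(seq_len(m), function(j) rbinom(n, 2, p[j]), numeric(n))
  if (n == 1) dos <- matrix(dos, nrow = 1)
  if (config$missing_rate > 0)
    dos[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_real_
  dimnames(dos) <- list(patient_ids, ids)
  variants <- data.frame(variant_id = ids, allele_a = al[, 1], allele_b = al[, 2],
                         hla = hla, freq_b = p, stringsAsFactors = FALSE)
  effect_is_b <- runif(m) < 0.5
  weights <- data.frame(
    variant_id = ids,
    effect_allele = ifelse(effect_is_b, al[, 2], al[, 1]),
    other_allele = ifelse(effect_is_b, al[, 1], al[, 2]),
    odds_ratio = exp(rnorm(m, 0, 0.15)),
    category = ifelse(hla, "HLA", "non-HLA"),
    stringsAsFactors = FALSE
  )
  list(genotypes = genotype_matrix(dos, variants), weights = weights)
}
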