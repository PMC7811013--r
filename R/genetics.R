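# Variant QC, allele-aligned polygenic risk scoring, and covariate-adjusted
# genetic association scans.

#' Construct a genotype matrix
#'
#' Per-patient allele dosages (values in \[0, 2\], NA for missing) with
#' per-variant metadata. Dosages count copies of `allele_b`.
#'
#' @param dosages numeric matrix, patients x variants, with dimnames.
#' @param variants data.frame with columns `variant_id`, `allele_a`,
#'   `allele_b` and optionally `hla` (logical); `variant_id` must be unique
#'   and match `colnames(dosages)`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages),
            all(c("variant_id", "allele_a", "allele_b") %in% names(variants)))
  if (anyDuplicated(variants$variant_id))
    stop("variant ids must be unique")
  if (!identical(colnames(dosages), variants$variant_id))
    stop("colnames(dosages) must equal variants$variant_id")
  if (any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
      stop("dosages must lie in [0, 2] or be missing")
  }
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d patients x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test given the allele counts: the p-value is the sum
#' of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Probabilities
#' over the admissible heterozygote counts (same parity as the minor
#' allele count) are computed by the stable ratio recurrence
#' \eqn{P(n_{AB}+2)/P(n_{AB}) = n_A n_B / ((n_{AB}+2)(n_{AB}+1))} applied
#' outward from an interior starting count, then normalized.
#'
#' @param n_aa,n_ab,n_bb genotype counts (non-negative integers).
#' @return p-value in \[0, 1\] (1 when fewer than two genotypes observed or
#'   one allele is absent).
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n < 2 || n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # admissible het counts, same parity
  probs <- numeric(length(hets))
  start <- which.min(abs(hets - rare * (n_a + n_b - rare) / (n_a + n_b)))
  probs[start] <- 1
  if (start < length(hets)) for (k in start:(length(hets) - 1L)) {
    h <- hets[k]
    naa <- (min(n_a, n_b) - h) / 2  # rare-homozygote count at h
    nbb <- n - naa - h
    # P(h+2)/P(h) = 4 naa nbb / ((h+2)(h+1))
    probs[k + 1L] <- probs[k] * 4 * naa * nbb / ((h + 2) * (h + 1))
  }
  if (start > 1) for (k in start:2L) {
    h <- hets[k]
    # P(h-2)/P(h) = h(h-1) / (4 (naa+1)(nbb+1))
    naa <- (min(n_a, n_b) - h) / 2
    nbb <- n - naa - h
    probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * (naa + 1) * (nbb + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Per-variant quality control
#'
#' Computes, for every variant, the minor allele frequency over non-missing
#' calls, the call rate, and the Hardy-Weinberg exact-test p-value on hard
#' calls (dosages that are whole 0/1/2 within tolerance; fractional dosages
#' are excluded from the HWE computation). A variant is kept when
#' `maf >= maf_min`, `call_rate >= call_rate_min` and `hwe_p >= hwe_min`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min,call_rate_min,hwe_min filter thresholds (defaults 0.01,
#'   0.98, 1e-6).
#' @return data.frame of class `qc_report` with per-variant `maf`,
#'   `call_rate`, `hwe_p`, `kept`, `reason`; per-filter exclusion counts in
#'   `attr(, "exclusions")`. Variants with no data are excluded with reason
#'   `"no data"`; a variant with no hard calls gets `hwe_p = NA` and the
#'   HWE filter is not applied to it.
#' @export
variant_qc <- function(genotypes, maf_min = 0.01, call_rate_min = 0.98,
                       hwe_min = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  n <- nrow(d)
  res <- lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == 0L)
      return(data.frame(maf = NA_real_, call_rate = 0, hwe_p = NA_real_))
    f <- sum(obs) / (2 * length(obs))
    hard <- obs[abs(obs - round(obs)) < 1e-6]
    hwe_p <- if (length(hard)) {
      g <- round(hard)
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    } else NA_real_
    data.frame(maf = min(f, 1 - f), call_rate = length(obs) / n, hwe_p = hwe_p)
  })
  rep <- do.call(rbind, res)
  rep <- cbind(variant_id = genotypes$variants$variant_id, rep,
               stringsAsFactors = FALSE)
  no_data <- rep$call_rate == 0
  fail_maf <- !no_data & rep$maf < maf_min
  fail_cr <- !no_data & rep$call_rate < call_rate_min
  fail_hwe <- !no_data & !is.na(rep$hwe_p) & rep$hwe_p < hwe_min
  rep$kept <- !(no_data | fail_maf | fail_cr | fail_hwe)
  rep$reason <- ifelse(no_data, "no data",
                ifelse(fail_maf & fail_cr, "maf;call_rate",
                ifelse(fail_maf, "maf",
                ifelse(fail_cr, "call_rate",
                ifelse(fail_hwe, "hwe", "")))))
  attr(rep, "exclusions") <- c(no_data = sum(no_data), maf = sum(fail_maf),
                               call_rate = sum(fail_cr), hwe = sum(fail_hwe))
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Align genotype dosages to risk-increasing effect alleles
#'
#' Matches each weight-table row to its genotype variant by id, requires
#' the allele pairs to agree as a set (otherwise the variant is dropped
#' with a logged reason; strand resolution is out of scope), reflects
#' dosages (`2 - d`) where the effect allele is the genotype's A allele,
#' and inverts odds ratios below 1 (swapping effect/other allele) so that
#' every stored log-odds-ratio weight is >= 0 and every dosage counts the
#' risk-increasing allele.
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `odds_ratio` (> 0) and optionally `category`
#'   ("HLA"/"non-HLA").
#' @return list of class `aligned_genotypes`: `dosages` (patients x kept
#'   variants, risk-allele counts), `weights` (kept rows with
#'   `risk_allele`, `log_or`, `category`), `dropped` (data.frame of
#'   variant_id + reason).
#' @export
align_effect_alleles <- function(genotypes, weights) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("variant_id", "effect_allele", "other_allele",
                  "odds_ratio") %in% names(weights)))
  if (any(weights$odds_ratio <= 0)) stop("odds ratios must be > 0")
  v <- genotypes$variants
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- list()
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    j <- match(w$variant_id, v$variant_id)
    if (is.na(j)) {
      dropped <- rbind(dropped, data.frame(variant_id = w$variant_id,
                                           reason = "not genotyped"))
      next
    }
    if (!setequal(c(w$effect_allele, w$other_allele),
                  c(v$allele_a[j], v$allele_b[j]))) {
      dropped <- rbind(dropped, data.frame(variant_id = w$variant_id,
                                           reason = "allele mismatch"))
      next
    }
    eff <- w$effect_allele; oth <- w$other_allele; or <- w$odds_ratio
    if (or < 1) { tmp <- eff; eff <- oth; oth <- tmp; or <- 1 / or }
    d <- genotypes$dosages[, j]
    if (eff == v$allele_a[j]) d <- 2 - d  # dosage counts allele B by convention
    keep[[length(keep) + 1L]] <- list(
      id = w$variant_id, d = d, risk = eff, log_or = log(or),
      category = if ("category" %in% names(w)) w$category else NA_character_)
  }
  if (!length(keep)) stop("no variants survived allele alignment")
  dos <- do.call(cbind, lapply(keep, `[[`, "d"))
  colnames(dos) <- vapply(keep, `[[`, "", "id")
  rownames(dos) <- rownames(genotypes$dosages)
  wt <- data.frame(
    variant_id = colnames(dos),
    risk_allele = vapply(keep, `[[`, "", "risk"),
    log_or = vapply(keep, `[[`, 0, "log_or"),
    category = vapply(keep, `[[`, "", "category"),
    stringsAsFactors = FALSE)
  if (nrow(dropped))
    message("align_effect_alleles: dropped ", nrow(dropped), " variant(s): ",
            paste(sprintf("%s (%s)", dropped$variant_id, dropped$reason),
                  collapse = ", "))
  structure(list(dosages = dos, weights = wt, dropped = dropped),
            class = "aligned_genotypes")
}

#' Polygenic risk score
#'
#' Per-patient sum of risk-allele dosages weighted by the log odds ratio:
#' `score_i = sum_v d_iv * log(OR_v)` over the chosen variant subset. The
#' score is an unstandardized sum; missing dosages are skipped (the score
#' runs over that patient's observed variants).
#'
#' @param aligned an [align_effect_alleles()] result.
#' @param subset `"all"`, `"HLA"` or `"non-HLA"`.
#' @return named numeric vector of per-patient scores.
#' @export
compute_prs <- function(aligned, subset = c("all", "HLA", "non-HLA")) {
  stopifnot(inherits(aligned, "aligned_genotypes"))
  subset <- match.arg(subset)
  sel <- if (subset == "all") rep(TRUE, nrow(aligned$weights))
         else aligned$weights$category == subset
  if (!any(sel)) stop("domain error: empty variant subset '", subset, "'")
  d <- aligned$dosages[, sel, drop = FALSE]
  w <- aligned$weights$log_or[sel]
  d[is.na(d)] <- 0  # missing dosage: variant skipped for that patient
  setNames(as.vector(d %*% w), rownames(d))
}

#' Association of polygenic risk scores with MRI traits
#'
#' For every trait and each of the total, HLA and non-HLA scores, fits
#' `trait ~ score + age + gender + protocol` by OLS and reports the Wald
#' test for the score term.
#'
#' @param scores data.frame with `patient_id`, `prs_total`, `prs_hla`,
#'   `prs_nonhla`.
#' @param table per-patient trait table containing the traits plus
#'   `patient_id`, `age`, `gender`, `protocol`.
#' @param traits character vector of trait columns (default
#'   [trait_names()]).
#' @return data.frame of association rows (one per trait x score), columns
#'   as in [association_result()].
#' @export
prs_trait_association <- function(scores, table, traits = trait_names()) {
  df <- merge(table, scores, by = "patient_id")
  score_cols <- c(total = "prs_total", HLA = "prs_hla", `non-HLA` = "prs_nonhla")
  out <- list()
  for (tr in traits) for (sc in names(score_cols)) {
    out[[paste(tr, sc)]] <- covariate_adjusted_association(
      df, tr, score_cols[[sc]], covariates = c("age", "gender", "protocol"),
      predictor_label = paste0("prs_", sc))
  }
  do.call(rbind, out)
}

#' Single-variant association scan
#'
#' Additively-coded per-variant association: for every (variant, trait)
#' pair fits `trait ~ dosage + age + gender + protocol` and reports the
#' Wald p-value for the dosage term. Monomorphic variants (no dosage
#' variation among complete rows) are skipped and excluded from the
#' denominators. The nominal-significance fraction per variant category is
#' `100 * #(p < 0.05) / #tests`.
#'
#' @param aligned an [align_effect_alleles()] result.
#' @param table per-patient trait table (`patient_id`, `age`, `gender`,
#'   `protocol`, trait columns).
#' @param traits trait columns to scan (default [trait_names()]).
#' @param alpha nominal significance level (default 0.05).
#' @return list of class `variant_scan`: `results` (one row per test:
#'   variant_id, category, trait, beta, se, p, n), `nominal` (per category
#'   and overall: n_tests, n_nominal, nominal_fraction in percent),
#'   `n_skipped` monomorphic-test count.
#' @export
single_variant_scan <- function(aligned, table, traits = trait_names(),
                                alpha = 0.05) {
  stopifnot(inherits(aligned, "aligned_genotypes"))
  ids <- rownames(aligned$dosages)
  df0 <- table[match(ids, table$patient_id), , drop = FALSE]
  if (any(is.na(df0$patient_id))) stop("trait table lacks some genotyped patients")
  rows <- vector("list", ncol(aligned$dosages) * length(traits))
  k <- 0L; skipped <- 0L
  for (j in seq_len(ncol(aligned$dosages))) {
    dj <- aligned$dosages[, j]
    for (tr in traits) {
      df <- data.frame(y = df0[[tr]], dosage = dj, age = df0$age,
                       gender = df0$gender, protocol = df0$protocol)
      df <- df[complete.cases(df), , drop = FALSE]
      if (nrow(df) < 6 || var(df$dosage) == 0) { skipped <- skipped + 1L; next }
      fit <- lm(y ~ dosage + age + gender + protocol, data = df)
      sm <- summary(fit)$coefficients
      k <- k + 1L
      rows[[k]] <- data.frame(
        variant_id = aligned$weights$variant_id[j],
        category = aligned$weights$category[j], trait = tr,
        beta = sm["dosage", 1], se = sm["dosage", 2], p = sm["dosage", 4],
        n = nrow(df), stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    stop("no testable (polymorphic, complete) variant-trait pairs")
  results <- do.call(rbind, rows[seq_len(k)])
  nominal <- do.call(rbind, lapply(
    split(results, results$category), function(g)
      data.frame(category = g$category[1], n_tests = nrow(g),
                 n_nominal = sum(g$p < alpha),
                 nominal_fraction = 100 * sum(g$p < alpha) / nrow(g))))
  nominal <- rbind(nominal, data.frame(
    category = "all", n_tests = nrow(results),
    n_nominal = sum(results$p < alpha),
    nominal_fraction = 100 * sum(results$p < alpha) / nrow(results)))
  rownames(nominal) <- NULL
  structure(list(results = results, nominal = nominal, n_skipped = skipped),
            class = "variant_scan")
}

#' @export
print.variant_scan <- function(x, ...) {
  cat(sprintf("single-variant scan: %d tests (%d skipped)\n",
              nrow(x$results), x$n_skipped))
  print(x$nominal)
  invisible(x)
}
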